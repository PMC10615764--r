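# Two-cohort demo: one "consortium" per cohort, a planted thalamus-like hub
# effect, SVM classification with permutation testing, univariate stats.
# Run:  Rscript inst/cli/connclass.R all --config inst/extdata/demo_run.yaml --out demo_out
cohorts:
  cohortA:
    n_regions: 40
    n_per_group: 100
    n_sites: 3
    n_timepoints: 0
    hub_effect:
      region: 7
      d: 0.4
    consortium: A
  cohortB:
    n_regions: 40
    n_per_group: 100
    n_sites: 3
    n_timepoints: 0
    hub_effect:
      region: 7
      d: 0.4
    consortium: B
contrasts:
  - mdd_vs_hc
  - m_vs_f
models:
  - svm_linear
n_perms: 0
univariate: true
seed: 42
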