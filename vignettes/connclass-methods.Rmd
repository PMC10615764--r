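---
title: "Methods: simulating, classifying and attributing multi-site functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, classifying and attributing multi-site functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Resting-state functional connectivity (FC) — the matrix of Pearson
correlations between the fMRI time courses of R atlas regions — is a widely
used candidate biomarker for major depressive disorder (MDD). Multi-site
consortium studies classify patients against healthy controls (HC) from
these R x R matrices, test each of the P = R(R-1)/2 connections
univariately, and then ask *which* regions and connections carry the
discriminative signal. `connclass` implements that entire analysis chain —
cohort simulation, FC and graph construction, SVM and graph-convolutional
(GCN) classification under stratified cross-validation with permutation
testing, edge-mask and ablation attribution, and the mass-univariate stage —
as small, separately testable functions.

Consortium rs-fMRI data are access-restricted, so the package ships a
synthetic cohort generator whose statistical structure mirrors what the
downstream stages assume: small connection-wise case-control effects, a
larger multivariate sex effect, additive site (scanner) batch effects,
covariate coupling, and sampling noise consistent with finite scan length.
Every stage of the pipeline is exercised against cohorts with *known* ground
truth.

# The generator

Subjects are built in Fisher-z space (`z = atanh(r)`), where additive
effects are well-defined and the sampling SD of an empirical correlation is
approximately `1/sqrt(T - 3)` for T time points:

```
z_ij = base_ij + (g/2) d_ij s + (x/2) d^sex_ij s + site_ij + beta_age (age - 40)
       + beta_fd (fd - 0.15) + jitter_ij
```

with `g = +1` for MDD and `-1` for HC (so positive d means patients higher),
`x = +1` for male. The base connectome has a constant off-diagonal floor
(0.1), lobe-like blocks of elevated correlation (0.25, blocks of 14
regions) and elevated homotopic pairs (0.35) under an interleaved
left/right ordering; it is projected to the nearest correlation matrix
(alternating projections with Dykstra's correction, tolerance 1e-8) if the
construction is not positive semidefinite.

**Effect-size parameterization.** The natural inputs are Cohen's d
values, not raw shifts, so the planted z shift at a connection is
`d * s`, where `s` (`between_subject_sd`, default 0.1) is the **total**
between-subject SD of z-connectivity. The generator apportions `s^2` into
its components — site variance, measurement noise `1/(t_eff - 3)`, covariate
variance — and draws subject jitter with the remaining variance. Two
details make realized d match planted d closely: (i) the site contribution
is budgeted as `(1 - 1/k) site_sd^2` for k sites, the expected
within-cohort variance of k site offsets; (ii) the tanh back-transform
rescales the mean shift and the SD by the same local factor `1 - r^2`, so d
is invariant to first order. Configuration errors out if the components
exceed `s^2`.

**Two emission modes.** With `n_timepoints > 0`, a subject's target
correlation matrix is projected to the nearest positive definite
correlation matrix and T white multivariate normal samples are drawn;
the stored FC is the empirical correlation of that series. With
`n_timepoints <= 0` (the analytic mode used by most tests), measurement
noise of SD `1/sqrt(t_eff - 3)` is added directly in z and the FC is the
tanh back-transform. The analytic mode skips the PSD projection: the
back-transform already satisfies every container invariant (symmetry, unit
diagonal, entries in (-1, 1)), and skipping the projection keeps planted
effect sizes exact — projecting a strongly indefinite target visibly
attenuates planted mean shifts. Time series are temporally white by design;
FC distribution, not dynamics, is what the downstream stages consume.

**Severity.** Patient severity (HAM-D-like: baseline 20, clamped to
[0, 52]) is a linear function of the *measured* z-connectivity at 30 random
connections plus noise calibrated so the population R^2 is 0.05, inside the
few-percent band that FC typically explains. Coupling to the measured
(noisy) values rather than the latent subject values makes the stated R^2
attainable in principle by a regressor that sees the emitted FC; at T = 200
the measurement variance is comparable to the subject variance, so latent
coupling would halve the ceiling.

**Defaults** (chosen once, as plausible for multi-site MDD cohorts): sites
k = 4 with connection-wise offset SD 0.05; ages normal(40, 12) clamped to
[18, 70]; mean framewise displacement Gamma with mean 0.15 mm, SD 0.05 mm;
sexes 60/40 M/F; covariate slopes -8e-4 per year and -0.05 per mm on all
connections; a sex effect of |d| = 0.25 with random signs on 300 random
connections, which places sex classification well above diagnosis
classification — the qualitative pattern reported for real consortium data.

# Connectome construction

`pearson_fc()` computes the region-by-region Pearson matrix. SVM features
are the strictly-upper triangle in row-major lexicographic pair order
(`vectorize_upper()`; `upper_pairs()` documents the order). Graphs keep the
top `ceiling(0.5 P)` connections by **absolute** correlation as binary
edges — ties broken deterministically by lexicographic pair order, a stable
radix sort — and use each region's full pre-binarization FC row (diagonal
zeroed) as its node features. The GCN propagation operator is the
symmetric renormalization `D^(-1/2)(A + I)D^(-1/2)`. No Fisher transform is
applied to classifier features by default (`fc_features(fisher = TRUE)`
exposes the switch).

# Classification experiments

Each experiment is: balanced subsampling (majority class down-sampled to
the minority count, stratified by site via largest-remainder allocation);
stratified 5-fold CV (folds stratified jointly by class and site, falling
back to class-only with a warning when a stratum is smaller than k); and,
per fold, hyperparameter selection on a 20% holdout of the training split
— each grid point fitted on the remaining 80%, best balanced accuracy wins,
ties to the first grid row — before fitting on the full training split and
scoring the untouched test fold. A guard asserts train/test disjointness.

SVMs (linear and rbf) and the SVR are fitted with kernlab on precomputed
kernel matrices; the experiment computes one Gram matrix per kernel width
and slices it per fold, which makes the label-permutation test (features
fixed) inexpensive. The rbf width grid multiplies the `1/(P Var(X))` scale
heuristic by {0.1, 1, 10}; C runs over {0.01, 0.1, 1, 10, 100}.

The GCN is written in-package against base matrix algebra: stacked
convolutions `H <- relu(Ahat H W + b)` with per-unit biases initialized
slightly positive (0.1) so ReLU units start alive, mean pooling over nodes,
a dense output layer, binary cross entropy, minibatch Adam (batch 32) under
the step schedule (initial learning rate 1e-3, divided by 10 every 30
epochs, 100 epochs). Classifier training watches for dead-ReLU collapse
(constant output over the training set) and re-initializes from a derived
seed, at most twice. Subjects are batched through one sparse block-diagonal propagation
matrix, so a whole minibatch is two sparse-dense products per layer.
Weight initialization, batching and dropout are all seeded; still, GCN
results are asserted as across-seed bands, never single-run equalities.
The default schedule is sized for consortium-scale samples; experiments on
small simulated cohorts (a few hundred subjects) use a larger learning rate
(0.01) and smaller batches so the number of Adam steps is comparable —
passing budgets are stated with each experiment.

**Permutation test.** The observed statistic is the mean CV balanced
accuracy; each of B permutations shuffles labels globally (before
subsampling) and reruns the full CV (`mode = "refit"`, default; a cheap
`permute_test` mode only shuffles the test labels against stored
predictions). `p = (1 + #[perm >= obs]) / (1 + B)`; `bonferroni_adjust()`
multiplies by the number of experiments. Default B is 1000 for SVMs and 100
for GCNs.

**Cross-dataset transfer.** SVMs tune on a 20% holdout of the training
cohort and evaluate one-shot on the full (balanced) test cohort. GCNs score
each grid point on a held-out 20% of the test cohort and report the winner
on the remaining 80%.

**Severity.** `predict_severity()` runs site-stratified 5-fold CV on
patients and reports the pooled out-of-fold `R^2 = 1 - SSE/SST`, which is 0
for a constant predictor and negative when worse than the mean.

# Attribution

**Region ablation.** Per repeat: fresh subsample, fresh 80/20 split, fresh
GCN training; then, for every region, the region's row AND column of each
*test* subject's FC are zeroed (both, to preserve symmetry), graphs are
rebuilt — so the top-K edge set is recomputed on the masked matrix and the
region's features and incident edges vanish while the node itself stays —
and the drop in test balanced accuracy, in percentage points, is attributed
to the region. Means and SDs over repeats are reported; training is never
touched.

**Edge-mask explainer.** Per correctly classified subject, a mask
`M = sigmoid(theta)` over all P connections is optimized (Adam, learning
rate 0.05, 150 epochs) to minimize the cross-entropy of the masked model
output against the model's own unmasked predicted class, plus
`0.5 * mean(M)` (size) and `0.05 * mean(entropy(M))` (sharpness). Three
design choices matter, each forced by a failure mode observed on planted
ground truth:

1. *Joint gating.* The mask gates each connection in both the propagation
   matrix and the node-feature matrix. With mean pooling, renormalized
   self-loops and FC-row features, a trained GCN can read a hub effect
   entirely from the corresponding feature column, leaving predictions
   insensitive to every adjacency entry — an adjacency-only mask is then
   uninformative.
2. *Mean imputation.* A masked feature entry is set to the cohort mean
   profile, not to zero: masking removes a connection's information, not
   its value, so connections that are merely large for everyone carry no
   mask signal.
3. *Flipped-target control.* A mask that preserves a prediction still
   retains class-independent score-raising structure. Each subject
   therefore also contributes a control mask optimized toward the opposite
   class, and the ranking uses the mean of `m_own - m_flip`: structure
   kept or dropped regardless of target cancels, and only
   class-discriminative connections survive.

The size penalty dominates the entropy penalty so uninformative
connections decay to zero instead of saturating at one (an
entropy-dominant setting is bistable around the 0.5 initialization and
buries the signal). The reported mask is the mean own-target mask with
per-class means also emitted; explanations are computed on held-out
subjects, because on training subjects the mask faithfully keeps the
model's memorized noise directions, which can outrank the planted
connections.

**Consensus.** `rank_consensus()` intersects the top-k regions (ablation)
or edges (explainer) of two cohorts' results and orders the shared items by
mean rank — the replicated-findings rule.

# Mass-univariate stage

Features are residualized on sex, age, site and mean framewise
displacement by group-blind OLS over all subjects (one-hot with intercept;
rank deficiency errors out naming the collinear columns; the grand mean is
re-added). Connection-wise pooled-variance t-tests (Student rather than
Welch — the designs are balanced by construction), two-sided p from the t
distribution, Benjamini-Hochberg step-up FDR (hand-implemented, cross-
checked in tests against `stats::p.adjust` and a brute-force enumeration),
Cohen's d with the same positive-means-patients sign convention as the
generator, and per-region counts of significantly increased/decreased
connections. `combat_lite()` offers location-scale site harmonization
(per-connection site offsets and scales removed after protecting
covariates, optional shrinkage of site parameters toward their
across-connection means); it is a simplified variant for simulation work,
not a reference implementation.

One measurement subtlety, used when *testing* residualization: a site
classifier trained on residuals computed from the full sample scores
*below* chance, because joint centering leaves an anti-correlated artifact
in held-out folds. The package's calibration checks therefore estimate
residualization coefficients on the training fold only and apply them to
the test fold, which leaves the classifier at chance — the correct reading
of "no site information remains".

# Numerical and design notes

- Fisher transforms clamp correlations at `1 - 1e-7` to stay finite.
- `nearest_correlation()` caps at 500 sweeps and errors with the residual.
- Zero-variance connections: t = 0 and p = 1 with a flag; Cohen's d is NA
  with a warning; metric denominators of zero yield NA with a warning and
  balanced accuracy averages the available components.
- All experiment randomness derives from one seed via named child seeds
  (`child_seed(seed, stage)`), so adding a stage never shifts another
  stage's stream.
- The problem sizes used by the test suite — 112 regions throughout the
  calibration and recovery checks, with 100-1100 subjects per group
  depending on the statistical demand of each property, and 200
  permutations x 20 seeds for the null calibration — were chosen so each
  check has the power its tolerance implies.

# What passing tests do and do not show

The generator emulates the *distributional* structure the analyses assume:
connection-wise shifts of realistic magnitude, site batch offsets, covariate
coupling, and correlation-matrix geometry. It does not emulate hemodynamics,
temporal autocorrelation, motion artifacts, atlas misregistration, or
site-by-effect interactions; scanner effects are purely additive in z.
Passing the recovery and calibration suite therefore shows the pipeline is
statistically sound and faithful to its stated procedures — not that any
particular accuracy is attainable on real consortium data, where
heterogeneity is the dominant obstacle.

# Known limitations

- `combat_lite` is location-scale only; full empirical-Bayes harmonization
  across small sites is out of scope.
- The GCN is a compact spatial formulation (two to three renormalized
  convolutions, mean pooling); architecture search is limited to the
  declared grid.
- Stationary FC only: no dynamic (windowed) connectivity, partial
  correlation or tangent-space embedding.
- The ablation study masks test data only, per the stated procedure; models
  are never retrained on masked training data.
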