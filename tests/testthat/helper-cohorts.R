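# Shared fixtures: small generator configs and a per-session cohort cache so
# expensive cohorts are generated once and reused across test files.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- force(expr)
  .cohort_cache[[key]]
}

# Small analytic-mode config: no time series, fast.
small_config <- function(n_regions = 20, n_per_group = 50, n_sites = 2,
                         seed = 1, ...) {
  cohort_config(n_regions = n_regions, n_per_group = n_per_group,
                n_sites = n_sites, n_timepoints = 0, seed = seed, ...)
}

# Null config: no planted diagnosis, sex or severity structure (overridable).
null_config <- function(n_regions = 20, n_per_group = 50, n_sites = 2,
                        seed = 1, ...) {
  args <- utils::modifyList(
    list(n_regions = n_regions, n_per_group = n_per_group, n_sites = n_sites,
         n_timepoints = 0, seed = seed, planted_effects = NULL,
         hub_effect = NULL, sex_effect = NULL, severity_model = NULL),
    list(...))
  do.call(cohort_config, args)
}

one_point_rbf <- function() {
  model_spec("svm_rbf", grid = data.frame(C = 1, gamma_mult = 1))
}

# The full-size null cohorts shared by the calibration checks (112 regions,
# 100 per group, 4 sites, analytic mode).
null_cohort_112 <- function(seed) {
  cached(sprintf("null112_%d", seed), generate_cohort(
    cohort_config(n_regions = 112, n_per_group = 100, n_sites = 4,
                  n_timepoints = 0, planted_effects = NULL, hub_effect = NULL,
                  sex_effect = NULL, severity_model = NULL, seed = seed)))
}

# Run a small SVM CV on an arbitrary feature matrix / label pair using the
# package's folds, fitting and metrics (used e.g. for site classification on
# residualized features).
cv_binary_features <- function(x, y, sites = NULL, k = 5, seed = 1,
                               spec = one_point_rbf()) {
  folds <- make_folds(y, sites, k = k, seed = seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    m <- fit_model(x[tr, , drop = FALSE], droplevels(factor(y[tr])), spec,
                   seed = seed + f)
    evaluate_metrics(y[te], predict(m, x[te, , drop = FALSE]),
                     positive = levels(factor(y))[2])$balanced_accuracy
  }, numeric(1))
  mean(accs)
}
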