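# Classification experiments: contrasts, balanced subsampling, stratified
# 5-fold CV with an inner 20% tuning holdout, metric aggregation, permutation
# testing, cross-dataset transfer and severity regression.

#' Contrast specification
#'
#' The five built-in case-control contrasts, or a custom one. A contrast maps
#' a cohort manifest to a two-level factor (NA = subject excluded); the
#' second factor level is the positive class.
#'
#' @param name One of `"mdd_vs_hc"`, `"nonmed_vs_hc"`, `"med_vs_hc"`,
#'   `"med_vs_nonmed"`, `"m_vs_f"`, or any name when `labeller` is given.
#' @param labeller Optional function `manifest -> factor` for custom
#'   contrasts (e.g. site classification).
#' @return A `contrast_spec`.
#' @examples
#' contrast_spec("mdd_vs_hc")
#' @export
contrast_spec <- function(name, labeller = NULL) {
  builtin <- c("mdd_vs_hc", "nonmed_vs_hc", "med_vs_hc", "med_vs_nonmed",
               "m_vs_f")
  if (is.null(labeller)) {
    name <- match.arg(name, builtin)
    labeller <- switch(name,
      mdd_vs_hc = function(m) factor(m$diagnosis, levels = c("HC", "MDD")),
      nonmed_vs_hc = function(m) {
        lab <- ifelse(m$diagnosis == "HC", "HC",
                      ifelse(!is.na(m$medicated) & !m$medicated, "MDD", NA))
        factor(lab, levels = c("HC", "MDD"))
      },
      med_vs_hc = function(m) {
        lab <- ifelse(m$diagnosis == "HC", "HC",
                      ifelse(!is.na(m$medicated) & m$medicated, "MDD", NA))
        factor(lab, levels = c("HC", "MDD"))
      },
      med_vs_nonmed = function(m) {
        lab <- ifelse(m$diagnosis == "MDD" & !is.na(m$medicated),
                      ifelse(m$medicated, "med", "nonmed"), NA)
        factor(lab, levels = c("nonmed", "med"))
      },
      m_vs_f = function(m) factor(m$sex, levels = c("F", "M")))
  }
  structure(list(name = name, labeller = labeller), class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat(sprintf("<contrast_spec> %s\n", x$name)); invisible(x)
}

contrast_labels <- function(contrast, manifest) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  stopifnot(inherits(contrast, "contrast_spec"))
  lab <- contrast$labeller(manifest)
  if (!is.factor(lab) || nlevels(lab) != 2) {
    abort_bad_arg("contrast labeller must return a two-level factor.")
  }
  lab
}

# Down-sample the majority class to the minority count, stratified by site
# (largest-remainder allocation proportional to the majority's per-site
# counts, capped by availability). Returns row indices into `labels`.
balance_indices <- function(labels, sites, seed) {
  keep <- which(!is.na(labels))
  if (length(keep) == 0) abort_bad_arg("no labelled subjects for contrast.")
  tab <- table(labels[keep])
  if (any(tab == 0)) abort_bad_arg("a contrast class is empty.")
  if (tab[1] == tab[2]) return(keep)
  set.seed(seed)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  n_target <- min(tab)
  maj_idx <- keep[labels[keep] == majority]
  maj_sites <- sites[maj_idx]
  counts <- table(maj_sites)
  quota <- n_target * counts / sum(counts)
  alloc <- floor(quota)
  rem <- n_target - sum(alloc)
  if (rem > 0) {
    frac_order <- order(quota - alloc, decreasing = TRUE)
    alloc[frac_order[seq_len(rem)]] <- alloc[frac_order[seq_len(rem)]] + 1
  }
  over <- pmax(alloc - counts, 0)
  alloc <- pmin(alloc, counts)
  while (sum(over) > 0) {
    room <- which(alloc < counts)
    give <- room[order(counts[room] - alloc[room], decreasing = TRUE)][1]
    alloc[give] <- alloc[give] + 1
    over[which(over > 0)[1]] <- over[which(over > 0)[1]] - 1
  }
  picked <- unlist(lapply(names(counts), function(s) {
    pool <- maj_idx[maj_sites == s]
    sample(pool, alloc[[s]])
  }), use.names = FALSE)
  sort(c(keep[labels[keep] == minority], picked))
}

#' Balanced subsampling of a cohort for a contrast
#'
#' Randomly down-samples the majority class to the minority-class count so
#' both classes are equal, stratified by site where possible; subjects the
#' contrast excludes are dropped. Deterministic given `seed`.
#'
#' @param cohort An `fc_cohort`.
#' @param contrast A [contrast_spec()] or contrast name.
#' @param seed Subsampling seed.
#' @return The subsampled `fc_cohort`.
#' @export
subsample_balanced <- function(cohort, contrast, seed = 1L) {
  labels <- contrast_labels(contrast, cohort$manifest)
  idx <- balance_indices(labels, cohort$manifest$site, seed)
  subset_cohort(cohort, idx)
}

#' Stratified cross-validation folds
#'
#' Assigns each subject to exactly one of `k` test folds, stratified jointly
#' by class and site: within each (class, site) stratum subjects are
#' shuffled and dealt to folds cyclically from a random offset, so fold
#' sizes differ by at most one per stratum. If any stratum is smaller than
#' `k`, stratification falls back to class only, with a warning.
#'
#' @param labels Class factor (no NAs).
#' @param sites Optional site ids (same length).
#' @param k Number of folds (default 5).
#' @param seed Seed.
#' @return Integer vector of fold assignments in `1:k`.
#' @export
make_folds <- function(labels, sites = NULL, k = 5L, seed = 1L) {
  n <- length(labels)
  if (n < k) abort_bad_arg("need at least k subjects.")
  set.seed(seed)
  strata <- if (is.null(sites)) factor(labels) else
    interaction(labels, sites, drop = TRUE)
  if (!is.null(sites) && min(table(strata)) < k) {
    warning("a (class, site) stratum is smaller than k; ",
            "falling back to class-only stratification.", call. = FALSE)
    strata <- factor(labels)
  }
  folds <- integer(n)
  for (s in levels(strata)) {
    idx <- sample(which(strata == s))
    offset <- sample.int(k, 1) - 1L
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
  }
  folds
}

#' Classification metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), balanced accuracy =
#' their mean, F1 = 2TP/(2TP+FP+FN). A metric with a zero denominator is
#' reported as `NA` with a warning (and balanced accuracy averages the
#' available components).
#'
#' @param truth Factor/vector of true labels.
#' @param pred Factor/vector of predicted labels.
#' @param positive Label of the positive class (default: second factor level
#'   of `truth`).
#' @return One-row tibble with the four metrics and the confusion counts.
#' @examples
#' evaluate_metrics(c("a","a","a","a","b","b","b","b"),
#'                  c("a","a","a","b","a","a","b","b"), positive = "b")
#' @export
evaluate_metrics <- function(truth, pred, positive = NULL) {
  if (length(truth) == 0) abort_bad_arg("empty input.")
  if (length(truth) != length(pred)) abort_bad_arg("length mismatch.")
  truth <- as.character(truth); pred <- as.character(pred)
  positive <- positive %||% {
    lv <- sort(unique(truth)); lv[length(lv)]
  }
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens) || is.na(spec)) {
    warning("a class is absent from `truth`; affected metrics are NA.",
            call. = FALSE)
  }
  bal <- mean(c(sens, spec), na.rm = TRUE)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  tibble::tibble(balanced_accuracy = bal, f1 = f1, sensitivity = sens,
                 specificity = spec, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Hyperparameter selection on a 20% tuning holdout
#'
#' Holds out 20% of the training split (stratified by class and site), fits
#' every grid point on the remaining 80%, and returns the grid point with the
#' best balanced accuracy (classification) or lowest mean squared error
#' (regression) on the holdout; exact ties are broken by grid order. A
#' one-point grid is returned immediately without fitting.
#'
#' @param engine Internal model engine (or build one via [fit_model()]'s
#'   machinery); exposed mainly for the experiment drivers.
#' @param idx Training indices.
#' @param y Full label vector (indexed by `idx`).
#' @param grid Hyperparameter grid.
#' @param sites Optional site vector for stratification.
#' @param seed Seed.
#' @param positive Positive class label.
#' @return List with `hyper` (chosen row) and `scores`.
#' @keywords internal
tune_hyperparameters <- function(engine, idx, y, grid, sites = NULL,
                                 seed = 1L, positive = NULL) {
  if (nrow(grid) == 0) abort_bad_arg("hyperparameter grid is empty.")
  if (nrow(grid) == 1) return(list(hyper = grid[1, , drop = FALSE], scores = NA))
  if (length(idx) < 10) abort_bad_arg("training split too small to tune (< 10).")
  regression <- is_regression_family(engine$family)
  folds <- make_folds(if (regression) rep("all", length(idx)) else y[idx],
                      sites = if (is.null(sites)) NULL else sites[idx],
                      k = 5L, seed = seed)
  hold <- idx[folds == 1L]
  fit_idx <- idx[folds != 1L]
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    m <- engine$fit(fit_idx, y[fit_idx], grid[g, , drop = FALSE],
                    seed = child_seed(seed, sprintf("tune%d", g)))
    pred <- engine$predict(m, hold)
    if (regression) {
      -mean((as.numeric(pred) - y[hold])^2)
    } else {
      evaluate_metrics(y[hold], pred, positive)$balanced_accuracy
    }
  }, numeric(1))
  list(hyper = grid[which.max(scores), , drop = FALSE], scores = scores)
}

# Core CV loop over a prebuilt engine. `labels` is a factor over all engine
# subjects with NA = excluded; subsampling and folds are derived from it.
run_cv_core <- function(engine, labels, sites, k = 5L, seed = 1L,
                        subsample = TRUE, tune = TRUE) {
  positive <- levels(labels)[2]
  idx <- if (subsample) balance_indices(labels, sites, child_seed(seed, "subsample"))
         else which(!is.na(labels))
  y <- labels
  folds <- make_folds(y[idx], sites[idx], k = k, seed = child_seed(seed, "folds"))
  fold_rows <- vector("list", k)
  predictions <- vector("list", k)
  for (f in seq_len(k)) {
    idx_te <- idx[folds == f]
    idx_tr <- idx[folds != f]
    stopifnot(length(intersect(idx_tr, idx_te)) == 0)  # leakage guard
    hyper <- if (tune && nrow(engine$spec$grid) > 1) {
      tune_hyperparameters(engine, idx_tr, y, engine$spec$grid, sites,
                           seed = child_seed(seed, sprintf("tune_f%d", f)),
                           positive = positive)$hyper
    } else {
      engine$spec$grid[1, , drop = FALSE]
    }
    m <- engine$fit(idx_tr, y[idx_tr], hyper,
                    seed = child_seed(seed, sprintf("fit_f%d", f)))
    pred <- engine$predict(m, idx_te)
    met <- evaluate_metrics(y[idx_te], pred, positive)
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n_test = length(idx_te)), met,
      tibble::tibble(hyper = list(hyper)))
    predictions[[f]] <- tibble::tibble(index = idx_te,
                                       truth = as.character(y[idx_te]),
                                       pred = as.character(pred))
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  structure(list(
    folds = folds_tbl,
    mean_balanced_accuracy = mean(folds_tbl$balanced_accuracy),
    sd_balanced_accuracy = stats::sd(folds_tbl$balanced_accuracy),
    predictions = dplyr::bind_rows(predictions),
    positive = positive, k = k, seed = seed,
    n = length(idx), family = engine$family,
    p_value = NA_real_, n_perms = 0L), class = "cv_result")
}

#' Run a cross-validated classification experiment
#'
#' The full experiment for one contrast and one model family: balanced
#' subsampling, stratified k-fold CV, per-fold hyperparameter tuning on a 20%
#' holdout of the training split, fitting, and test-fold evaluation. No test
#' subject ever enters tuning or fitting for its fold. All randomness derives
#' from `seed`.
#'
#' @param cohort An `fc_cohort`.
#' @param contrast A [contrast_spec()] or name.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5).
#' @param seed Experiment seed.
#' @param subsample Balance classes first? Default `TRUE`.
#' @return A `cv_result`: per-fold metrics tibble (`folds`), mean/SD balanced
#'   accuracy, pooled out-of-fold predictions, and (after
#'   [permutation_test()]) a permutation p-value. Use [generics::tidy()] /
#'   [generics::glance()] on it.
#' @export
run_cv_experiment <- function(cohort, contrast, spec, k = 5L, seed = 1L,
                              subsample = TRUE) {
  stopifnot(inherits(cohort, "fc_cohort"), inherits(spec, "model_spec"))
  labels <- contrast_labels(contrast, cohort$manifest)
  engine <- build_engine(spec, cohort)
  res <- run_cv_core(engine, labels, cohort$manifest$site, k = k, seed = seed,
                     subsample = subsample)
  res$contrast <- if (is.character(contrast)) contrast else contrast$name
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s: balanced accuracy %.3f (sd %.3f), n = %d\n",
              x$contrast %||% "?", x$family, x$mean_balanced_accuracy,
              x$sd_balanced_accuracy, x$n))
  if (x$n_perms > 0) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n", x$p_value, x$n_perms))
  }
  invisible(x)
}

#' Permutation test of a CV experiment
#'
#' The observed statistic is the mean CV balanced accuracy. Under the default
#' `mode = "refit"`, each permutation shuffles the contrast labels globally
#' (before subsampling) and reruns the entire CV experiment; under
#' `mode = "permute_test"` the observed out-of-fold predictions are kept and
#' only the test labels are shuffled. The p-value is
#' `(1 + #[perm >= observed]) / (1 + n_perms)`.
#'
#' @inheritParams run_cv_experiment
#' @param n_perms Number of permutations (>= 19).
#' @param mode `"refit"` (default) or `"permute_test"`.
#' @param alpha Significance level used only to warn when `n_perms` is too
#'   small to reach it.
#' @return The observed `cv_result` with `p_value`, `n_perms` and
#'   `perm_stats` filled in.
#' @export
permutation_test <- function(cohort, contrast, spec, n_perms = 1000L,
                             k = 5L, seed = 1L,
                             mode = c("refit", "permute_test"),
                             alpha = 0.05) {
  mode <- match.arg(mode)
  n_perms <- check_count(n_perms, "n_perms", min = 19L)
  if (1 / (1 + n_perms) > alpha) {
    warning(sprintf("n_perms = %d cannot reach alpha = %g.", n_perms, alpha),
            call. = FALSE)
  }
  labels <- contrast_labels(contrast, cohort$manifest)
  sites <- cohort$manifest$site
  engine <- build_engine(spec, cohort)
  observed <- run_cv_core(engine, labels, sites, k = k, seed = seed)
  obs_stat <- observed$mean_balanced_accuracy
  lab_idx <- which(!is.na(labels))
  perm_stats <- vapply(seq_len(n_perms), function(b) {
    pseed <- child_seed(seed, sprintf("perm%d", b))
    set.seed(pseed)
    perm <- labels
    perm[lab_idx] <- sample(labels[lab_idx])
    if (mode == "refit") {
      run_cv_core(engine, perm, sites, k = k,
                  seed = pseed)$mean_balanced_accuracy
    } else {
      pr <- observed$predictions
      shuffled <- sample(pr$truth)
      evaluate_metrics(shuffled, pr$pred, observed$positive)$balanced_accuracy
    }
  }, numeric(1))
  observed$p_value <- (1 + sum(perm_stats >= obs_stat)) / (1 + n_perms)
  observed$n_perms <- n_perms
  observed$perm_stats <- perm_stats
  observed$perm_mode <- mode
  observed$contrast <- if (is.character(contrast)) contrast else contrast$name
  observed
}

#' Bonferroni adjustment across experiments
#'
#' Multiplies a permutation p-value by the number of experiments in the run,
#' capped at 1.
#'
#' @param p P-value(s).
#' @param n_experiments Number of experiments compared.
#' @return Adjusted p-value(s).
#' @examples
#' bonferroni_adjust(0.01, 15)
#' @export
bonferroni_adjust <- function(p, n_experiments) pmin(1, p * n_experiments)

#' Cross-dataset transfer evaluation
#'
#' Trains on one cohort and evaluates on the other (both balanced-subsampled
#' first). SVM path: hyperparameters chosen on a 20% holdout of the training
#' cohort, one-shot evaluation on the full test cohort. GCN path: for each
#' grid point a model is trained on the full training cohort and scored on a
#' held-out 20% of the test cohort (stratified 5-fold split); the best is
#' evaluated on the remaining 80%.
#'
#' @param train_cohort,test_cohort `fc_cohort`s with identical region labels.
#' @param spec A [model_spec()].
#' @param contrast Contrast (default `"mdd_vs_hc"`).
#' @param seed Seed.
#' @return One-row metrics tibble (see [evaluate_metrics()]) plus the chosen
#'   hyperparameters as an attribute.
#' @export
cross_dataset_eval <- function(train_cohort, test_cohort, spec,
                               contrast = "mdd_vs_hc", seed = 1L) {
  if (!identical(train_cohort$region_labels, test_cohort$region_labels)) {
    abort_bad_arg("region labels differ between cohorts.")
  }
  a <- subsample_balanced(train_cohort, contrast, child_seed(seed, "sub_a"))
  b <- subsample_balanced(test_cohort, contrast, child_seed(seed, "sub_b"))
  y_a <- contrast_labels(contrast, a$manifest)
  y_b <- contrast_labels(contrast, b$manifest)
  positive <- levels(y_a)[2]

  if (is_gcn_family(spec$family)) {
    graphs_a <- cohort_graphs(a, spec$sparsity)
    graphs_b <- cohort_graphs(b, spec$sparsity)
    sel_folds <- make_folds(y_b, b$manifest$site, k = 5L,
                            seed = child_seed(seed, "b_select"))
    sel <- which(sel_folds == 1L)
    eval_idx <- which(sel_folds != 1L)
    grid <- spec$grid
    scores <- vapply(seq_len(nrow(grid)), function(g) {
      m <- gcn_train(graphs_a, y_a,
                     hidden = grid$hidden[g] %||% spec$hidden,
                     n_layers = grid$n_layers[g] %||% spec$n_layers,
                     epochs = spec$epochs, lr = spec$lr,
                     decay_every = spec$decay_every,
                     decay_factor = spec$decay_factor, dropout = spec$dropout,
                     batch_size = spec$batch_size,
                     seed = child_seed(seed, sprintf("xg%d", g)))
      pred <- factor(m$levels[(gcn_predict(m, graphs_b[sel]) >= 0.5) + 1L],
                     levels = m$levels)
      evaluate_metrics(y_b[sel], pred, positive)$balanced_accuracy
    }, numeric(1))
    g <- which.max(scores)
    m <- gcn_train(graphs_a, y_a,
                   hidden = grid$hidden[g] %||% spec$hidden,
                   n_layers = grid$n_layers[g] %||% spec$n_layers,
                   epochs = spec$epochs, lr = spec$lr,
                   decay_every = spec$decay_every,
                   decay_factor = spec$decay_factor, dropout = spec$dropout,
                   batch_size = spec$batch_size,
                   seed = child_seed(seed, sprintf("xg%d", g)))
    pred <- factor(m$levels[(gcn_predict(m, graphs_b[eval_idx]) >= 0.5) + 1L],
                   levels = m$levels)
    out <- evaluate_metrics(y_b[eval_idx], pred, positive)
    attr(out, "hyper") <- grid[g, , drop = FALSE]
    return(out)
  }

  x_a <- fc_features(a)
  x_b <- fc_features(b)
  engine <- build_svm_engine(spec, x_a)
  tuned <- tune_hyperparameters(engine, seq_len(nrow(x_a)), y_a, spec$grid,
                                sites = a$manifest$site,
                                seed = child_seed(seed, "xtune"),
                                positive = positive)
  model <- fit_model(x_a, y_a, spec, hyper = tuned$hyper,
                     seed = child_seed(seed, "xfit"))
  pred <- predict(model, x_b)
  out <- evaluate_metrics(y_b, pred, positive)
  attr(out, "hyper") <- tuned$hyper
  out
}

# Out-of-fold R^2 against the pooled mean: 1 - SSE/SST (may be negative).
oof_r_squared <- function(truth, pred) {
  sst <- sum((truth - mean(truth))^2)
  1 - sum((truth - pred)^2) / sst
}

#' Severity regression from FC
#'
#' Predicts patient symptom severity from connectivity with 5-fold CV
#' (site-stratified folds) and reports the pooled out-of-fold R^2,
#' `1 - SSE/SST` (negative when the model does worse than predicting the
#' mean; a constant predictor scores exactly 0 by this definition).
#'
#' @param cohort An `fc_cohort`; only subjects with `diagnosis == "MDD"` and
#'   non-missing severity are used.
#' @param spec A [model_spec()] with family `"svr_rbf"` or `"gcn_regressor"`.
#' @param k Folds (default 5).
#' @param seed Seed.
#' @return A `severity_result`: list with `r_squared`, per-fold tibble, and
#'   the reference baseline R^2 of 0 for the trivial mean predictor.
#' @export
predict_severity <- function(cohort, spec = model_spec("svr_rbf"), k = 5L,
                             seed = 1L) {
  stopifnot(is_regression_family(spec$family))
  m <- cohort$manifest
  idx_pat <- which(m$diagnosis == "MDD" & !is.na(m$severity))
  if (length(idx_pat) < k) abort_bad_arg("not enough patients with severity.")
  y <- m$severity[idx_pat]
  if (stats::sd(y) == 0) abort_bad_arg("severity has zero variance.")
  pats <- subset_cohort(cohort, idx_pat)
  engine <- build_engine(spec, pats)
  folds <- make_folds(rep("all", length(y)), pats$manifest$site, k = k,
                      seed = child_seed(seed, "folds"))
  pred <- numeric(length(y))
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    hyper <- if (nrow(spec$grid) > 1) {
      tune_hyperparameters(engine, tr, y, spec$grid, pats$manifest$site,
                           seed = child_seed(seed, sprintf("tune%d", f)))$hyper
    } else spec$grid[1, , drop = FALSE]
    mod <- engine$fit(tr, y[tr], hyper, seed = child_seed(seed, sprintf("fit%d", f)))
    pred[te] <- as.numeric(engine$predict(mod, te))
    fold_rows[[f]] <- tibble::tibble(fold = f, n_test = length(te),
                                     r_squared = oof_r_squared(y[te], pred[te]),
                                     hyper = list(hyper))
  }
  structure(list(r_squared = oof_r_squared(y, pred),
                 folds = dplyr::bind_rows(fold_rows),
                 baseline_r_squared = 0,
                 n_patients = length(y), family = spec$family, seed = seed),
            class = "severity_result")
}

#' @export
print.severity_result <- function(x, ...) {
  cat(sprintf("<severity_result> %s: out-of-fold R^2 = %.4f (n = %d patients)\n",
              x$family, x$r_squared, x$n_patients))
  invisible(x)
}
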