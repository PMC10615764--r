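# Classification experiments: subsampling, folds, tuning, metrics, CV,
# permutation testing, transfer and severity regression.

test_that("subsample_balanced equalizes classes, stratified by site", {
  co <- generate_cohort(null_config(n_regions = 10, n_per_group = 60,
                                    n_sites = 3, seed = 1))
  # drop 30 MDD -> 30 MDD vs 60 HC
  drop <- which(co$manifest$diagnosis == "MDD")[1:30]
  unb <- connclass:::subset_cohort(co, setdiff(seq_len(120), drop))
  sub <- subsample_balanced(unb, "mdd_vs_hc", seed = 3)
  expect_equal(as.integer(table(sub$manifest$diagnosis)), c(30L, 30L))
  # retained HC per site tracks the available per-site counts within 1
  hc_sites <- table(sub$manifest$site[sub$manifest$diagnosis == "HC"])
  avail <- table(unb$manifest$site[unb$manifest$diagnosis == "HC"])
  expect_true(all(abs(hc_sites - 30 * avail / 60) <= 1))

  # already balanced: membership unchanged
  sub2 <- subsample_balanced(co, "mdd_vs_hc", seed = 3)
  expect_identical(sub2$manifest$subject_id, co$manifest$subject_id)
})

test_that("folds partition the data and respect (class, site) strata", {
  y <- factor(rep(c("a", "b"), each = 50))
  f <- make_folds(y, k = 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 20))
  expect_true(all(table(f, y) == 10))

  sites <- rep(rep(c("s1", "s2"), each = 25), 2)
  f2 <- make_folds(y, sites, k = 5, seed = 2)
  expect_true(all(table(f2, interaction(y, sites)) == 5))

  # small stratum falls back to class-only stratification
  y3 <- factor(rep(c("a", "b"), each = 10))
  s3 <- c(rep("s1", 9), "s2", rep("s1", 10))
  expect_warning(make_folds(y3, s3, k = 5, seed = 3), "stratum")
})

test_that("evaluate_metrics matches hand values and brute-force counting", {
  # TP=3, FN=1, TN=2, FP=2 -> sens .75, spec .5, balanced .625
  truth <- c("p", "p", "p", "p", "n", "n", "n", "n")
  pred <- c("p", "p", "p", "n", "p", "p", "n", "n")
  m <- evaluate_metrics(truth, pred, positive = "p")
  expect_equal(m$balanced_accuracy, 0.625)
  expect_equal(m$f1, 2 * 3 / (2 * 3 + 2 + 1))

  # degenerate predictions on balanced truth
  all_pos <- evaluate_metrics(truth, rep("p", 8), positive = "p")
  expect_equal(all_pos$balanced_accuracy, 0.5)
  perfect <- evaluate_metrics(truth, truth, positive = "p")
  expect_true(all(unlist(perfect[1, 1:4]) == 1))
  expect_error(evaluate_metrics(character(0), character(0)), "empty")

  set.seed(4)
  for (rep in 1:1000) {
    n <- sample(4:30, 1)
    tr <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(tr)) < 2) next
    pr <- sample(c("p", "n"), n, replace = TRUE)
    got <- evaluate_metrics(tr, pr, positive = "p")
    want <- oracle_confusion_metrics(tr, pr, "p")
    expect_identical(unname(unlist(got[1, 1:4])), unname(want))
  }
})

test_that("tuning holds out 20%, picks the better grid point, breaks ties first", {
  co <- generate_cohort(null_config(n_regions = 10, n_per_group = 40,
                                    hub_effect = list(region = 3, d = 1.5),
                                    seed = 5))
  y <- contrast_labels(contrast_spec("mdd_vs_hc"), co$manifest)
  # first grid point memorizes (absurd kernel width), second generalizes
  spec <- model_spec("svm_rbf", grid = data.frame(C = c(10, 10),
                                                  gamma_mult = c(1e5, 1)))
  engine <- connclass:::build_engine(spec, co)

  # a one-point grid short-circuits
  one <- connclass:::tune_hyperparameters(NULL, 1:80, y,
                                          data.frame(C = 7), seed = 1)
  expect_equal(one$hyper$C, 7)

  # the adequately regularized point wins nearly always on separable data
  wins <- vapply(1:20, function(s) {
    connclass:::tune_hyperparameters(engine, seq_len(80), y, spec$grid,
                                     co$manifest$site, seed = s)$hyper$gamma_mult
  }, numeric(1))
  expect_gte(mean(wins == 1), 0.9)

  # exact ties return the first grid row
  tie_grid <- data.frame(C = c(5, 5), gamma_mult = c(1, 1))
  tied <- connclass:::tune_hyperparameters(engine, seq_len(80), y, tie_grid,
                                           co$manifest$site, seed = 2)
  expect_identical(as.numeric(rownames(tied$hyper)), 1)
})

test_that("null cohorts classify at chance; planted effects are learnable", {
  accs <- vapply(1:10, function(s) {
    co <- cached(sprintf("null20_%d", s),
                 generate_cohort(null_config(n_regions = 20, n_per_group = 100,
                                             n_sites = 2, seed = 300 + s)))
    run_cv_experiment(co, "mdd_vs_hc", one_point_rbf(),
                      seed = s)$mean_balanced_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.42)
  expect_lt(mean(accs), 0.58)

  eff <- vapply(1:3, function(s) {
    co <- generate_cohort(null_config(n_regions = 20, n_per_group = 200,
                                      n_sites = 2,
                                      hub_effect = list(region = 4, d = 0.5),
                                      seed = 400 + s))
    run_cv_experiment(co, "mdd_vs_hc", one_point_rbf(),
                      seed = s)$mean_balanced_accuracy
  }, numeric(1))
  expect_gt(mean(eff), 0.65)
})

test_that("permutation p-values follow the add-one formula and calibrate", {
  co <- generate_cohort(null_config(n_regions = 10, n_per_group = 50,
                                    n_sites = 1,
                                    hub_effect = list(region = 2, d = 2),
                                    seed = 6))
  # strong effect: observed beats all B permutations -> p = 1/(B+1)
  pt <- permutation_test(co, "mdd_vs_hc", one_point_rbf(), n_perms = 99,
                         seed = 1, mode = "permute_test")
  expect_equal(pt$p_value, 0.01)
  expect_equal(bonferroni_adjust(pt$p_value, 15), 0.15)
  expect_warning(
    permutation_test(co, "mdd_vs_hc", one_point_rbf(), n_perms = 19,
                     seed = 1, mode = "permute_test", alpha = 0.01),
    "cannot reach")

  # null calibration: p is roughly uniform across seeds
  frac <- mean(vapply(1:20, function(s) {
    con <- cached(sprintf("nullperm_%d", s),
                  generate_cohort(null_config(n_regions = 12, n_per_group = 30,
                                              n_sites = 1, seed = 500 + s)))
    permutation_test(con, "mdd_vs_hc", one_point_rbf(), n_perms = 39,
                     seed = s)$p_value < 0.25
  }, logical(1)))
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.5)
})

test_that("cross-dataset transfer works and validates region labels", {
  cfg_a <- null_config(n_regions = 15, n_per_group = 80, n_sites = 2,
                       hub_effect = list(region = 3, d = 0.8), seed = 7)
  cfg_b <- null_config(n_regions = 15, n_per_group = 80, n_sites = 2,
                       hub_effect = list(region = 3, d = 0.8), site_sd = 0.06,
                       seed = 8)
  a <- generate_cohort(cfg_a); b <- generate_cohort(cfg_b)
  spec <- model_spec("svm_linear", grid = data.frame(C = 1))

  # train = test reduces to resubstitution, at least as good as CV on average
  resub <- cross_dataset_eval(a, a, spec, seed = 1)$balanced_accuracy
  cv <- run_cv_experiment(a, "mdd_vs_hc", spec, seed = 1)$mean_balanced_accuracy
  expect_gte(resub, cv - 0.02)

  # a shifted replica transfers above chance
  tr <- cross_dataset_eval(a, b, spec, seed = 1)$balanced_accuracy
  expect_gt(tr, 0.55)

  bad <- b
  bad$region_labels <- paste0("X", bad$region_labels)
  expect_error(cross_dataset_eval(a, bad, spec), "region labels")
})

test_that("severity regression recovers exact signal and stays null on noise", {
  co <- generate_cohort(null_config(n_regions = 10, n_per_group = 120,
                                    n_sites = 2,
                                    severity_model = list(n_connections = 5,
                                                          r_squared = 0.05),
                                    seed = 9))
  # overwrite severity with an exact linear function of one connection
  fcv <- vapply(co$fc, function(m) m[1, 2], numeric(1))
  co$manifest$severity <- ifelse(co$manifest$diagnosis == "MDD",
                                 20 + 40 * fcv, NA)
  spec <- model_spec("svr_rbf", grid = tidyr::crossing(C = c(10, 100),
                                                       gamma_mult = c(0.1, 1)))
  res <- predict_severity(co, spec, seed = 1)
  expect_gt(res$r_squared, 0.9)

  # severity independent of FC: out-of-fold R^2 stays near/below zero
  r2 <- vapply(1:10, function(s) {
    con <- generate_cohort(null_config(n_regions = 10, n_per_group = 60,
                                       n_sites = 1, seed = 600 + s))
    con$manifest$severity <- ifelse(con$manifest$diagnosis == "MDD",
                                    rnorm(120, 20, 5), NA)
    predict_severity(con, model_spec("svr_rbf",
                                     grid = data.frame(C = 1, gamma_mult = 1)),
                     seed = s)$r_squared
  }, numeric(1))
  expect_lte(mean(r2), 0.02)

  # the definition gives a constant predictor exactly zero
  y <- c(3, 5, 9)
  expect_equal(connclass:::oof_r_squared(y, rep(mean(y), 3)), 0)

  con0 <- co
  con0$manifest$severity <- ifelse(con0$manifest$diagnosis == "MDD", 7, NA)
  expect_error(predict_severity(con0, spec), "zero variance")
})

test_that("sex contrast outperforms the diagnosis contrast on default cohorts", {
  accs <- vapply(1:2, function(s) {
    co <- generate_cohort(cohort_config(n_regions = 60, n_per_group = 100,
                                        n_sites = 2, n_timepoints = 0,
                                        seed = 700 + s))
    c(sex = run_cv_experiment(co, "m_vs_f", one_point_rbf(),
                              seed = s)$mean_balanced_accuracy,
      mdd = run_cv_experiment(co, "mdd_vs_hc", one_point_rbf(),
                              seed = s)$mean_balanced_accuracy)
  }, numeric(2))
  expect_gt(mean(accs["sex", ]), mean(accs["mdd", ]))
})
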