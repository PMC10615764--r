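# Mass-univariate stage: residualization, t-tests, FDR, Cohen's d,
# harmonization and region degree summaries.

test_that("residualize removes covariate structure exactly", {
  set.seed(1)
  n <- 60
  cov <- data.frame(age = rnorm(n, 40, 10), sex = sample(c("M", "F"), n, TRUE),
                    site = sample(c("s1", "s2"), n, TRUE))
  feat <- cbind(2 + 0.5 * cov$age, rnorm(n))
  res <- residualize(feat, cov)
  # a feature exactly linear in age becomes flat (grand mean re-added)
  expect_lt(max(abs(res[, 1] - mean(feat[, 1]))), 1e-10)
  # residuals (minus the re-added mean) orthogonal to every covariate column
  design <- model.matrix(~ ., cov)
  centered <- sweep(res, 2, colMeans(feat))
  expect_lt(max(abs(crossprod(design, centered))), 1e-8)
  # rank deficiency is reported with the collinear column
  cov$age2 <- cov$age * 2
  expect_error(residualize(feat, cov), "age2")
})

test_that("pooled t-test matches the hand formula", {
  feat <- matrix(c(1, 2, 3, 2, 3, 4), ncol = 1)
  groups <- factor(c("MDD", "MDD", "MDD", "HC", "HC", "HC"),
                   levels = c("HC", "MDD"))
  tt <- ttest_connections(feat, groups)
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)

  same <- matrix(rep(c(1, 2, 3), 2), ncol = 1)
  tt2 <- ttest_connections(same, groups)
  expect_equal(tt2$t, 0)
  expect_equal(tt2$p, 1, tolerance = 1e-12)

  const <- matrix(1, 6, 1)
  tt3 <- ttest_connections(const, groups)
  expect_true(tt3$zero_variance)
  expect_equal(tt3$p, 1)
})

test_that("null p-values are approximately uniform over all connections", {
  # site offsets are shared within site, so calibration is assessed on the
  # stage's own residualized features (site and covariates regressed out)
  ks <- vapply(1:3, function(s) {
    co <- generate_cohort(null_config(n_regions = 112, n_per_group = 500,
                                      n_sites = 4, seed = 100 + s))
    x <- residualize(fc_features(co),
                     co$manifest[, c("sex", "age", "site", "mean_fd")])
    tt <- ttest_connections(x, factor(co$manifest$diagnosis,
                                      levels = c("HC", "MDD")))
    suppressWarnings(stats::ks.test(tt$p, "punif")$statistic)
  }, numeric(1))
  expect_lt(mean(ks), 0.03)
})

test_that("fdr_bh matches hand cases, p.adjust and brute-force step-up", {
  r1 <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(r1$significant))
  r2 <- fdr_bh(c(0.04, 0.9, 0.9), q = 0.05)
  expect_false(any(r2$significant))
  r3 <- fdr_bh(0.04, q = 0.05)
  expect_true(r3$significant)
  expect_equal(r3$q_value, 0.04)
  expect_identical(nrow(fdr_bh(numeric(0))), 0L)

  set.seed(2)
  for (rep in 1:300) {
    m <- sample(1:40, 1)
    p <- round(runif(m), sample(c(1, 2, 6), 1))  # induce ties
    out <- fdr_bh(p, q = 0.05)
    expect_equal(out$q_value, stats::p.adjust(p, "BH"), tolerance = 1e-15)
    expect_identical(out$significant, oracle_bh_reject(p, 0.05))
    expect_true(all(out$q_value >= out$p))
  }
})

test_that("cohens_d_connections matches the pooled-SD formula", {
  feat <- matrix(c(1, 2, 3, 2, 3, 4), ncol = 1)
  groups <- factor(c("MDD", "MDD", "MDD", "HC", "HC", "HC"),
                   levels = c("HC", "MDD"))
  expect_equal(cohens_d_connections(feat, groups), c(-1))
  same <- matrix(rep(c(1, 2, 3), 2), ncol = 1)
  expect_equal(cohens_d_connections(same, groups), c(0))
  expect_warning(d0 <- cohens_d_connections(matrix(1, 6, 1), groups), "zero")
  expect_true(is.na(d0))
})

test_that("combat_lite removes site location effects and preserves groups", {
  set.seed(3)
  n <- 40; p <- 30
  x <- matrix(rnorm(n * p), n, p)
  site <- rep(c("a", "b"), each = n / 2)
  offs <- rnorm(p, 0, 2)
  x2 <- x
  x2[site == "b", ] <- sweep(x2[site == "b", ], 2, offs, `+`)
  h <- combat_lite(x2, site)
  expect_lt(max(abs(colMeans(h[site == "a", ]) - colMeans(h[site == "b", ]))),
            1e-8)

  # single site: identity
  expect_lt(max(abs(combat_lite(x, rep("a", n)) - x)), 1e-10)
  expect_error(combat_lite(x, c("a", rep("b", n - 1))), ">= 2")

  # a group effect orthogonal to site survives harmonization (small site
  # effects, so the removed site variance barely rescales d)
  co <- generate_cohort(null_config(
    n_regions = 20, n_per_group = 200, n_sites = 2, site_sd = 0.03,
    planted_effects = data.frame(i = 1:5, j = 6:10, d = 0.2), seed = 4))
  feats <- fc_features(co)
  g <- factor(co$manifest$diagnosis, levels = c("HC", "MDD"))
  d_before <- cohens_d_connections(feats, g)
  d_after <- cohens_d_connections(combat_lite(feats, co$manifest$site), g)
  pairs <- connclass:::upper_pairs(20)
  planted <- which(pairs$i %in% 1:5 & pairs$j == pairs$i + 5)
  expect_lt(max(abs(d_before[planted] - d_after[planted])), 0.02)
})

test_that("region degree summary counts incident significant connections", {
  r <- 6
  p <- r * (r - 1) / 2
  none <- region_degree_summary(rep(FALSE, p), rep(0, p), r)
  expect_true(all(none$n_increased == 0) && all(none$n_decreased == 0))

  sig <- rep(FALSE, p); d <- rep(0, p)
  sig[1] <- TRUE; d[1] <- 0.4   # connection (1, 2)
  one <- region_degree_summary(sig, d, r)
  expect_equal(one$n_increased[1:2], c(1, 1))
  expect_equal(sum(one$n_increased), 2)
})

test_that("a planted hub dominates the increased-degree summary", {
  co <- generate_cohort(null_config(
    n_regions = 30, n_per_group = 400, n_sites = 2,
    hub_effect = list(region = 7, d = 0.4), seed = 5))
  uv <- univariate_connections(co)
  deg <- uv$degrees
  expect_equal(which.max(deg$n_increased), 7)
  expect_gt(deg$n_increased[7], max(deg$n_increased[-7]))
})
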