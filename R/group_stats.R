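# Mass-univariate stage: covariate residualization, connection-wise pooled
# t-tests, Benjamini-Hochberg FDR, Cohen's d, region degree summaries, and a
# lightweight location-scale site harmonization.

#' Residualize features on nuisance covariates
#'
#' Ordinary least squares of every feature (connection) on the covariates
#' over ALL subjects, group-blind: categorical covariates (site, sex) are
#' one-hot encoded with an intercept, and the returned residuals have each
#' feature's grand mean added back. The group label is never a regressor.
#'
#' @param features n x P numeric matrix (subjects by connections).
#' @param covariates Data frame of nuisance covariates (e.g. sex, age, site,
#'   mean_fd); factors/characters are expanded to dummies.
#' @return n x P matrix of residualized features.
#' @export
residualize <- function(features, covariates) {
  features <- as.matrix(features)
  covariates <- as.data.frame(covariates, stringsAsFactors = TRUE)
  covariates[] <- lapply(covariates, function(c) {
    if (is.character(c) || is.logical(c)) factor(c) else c
  })
  design <- stats::model.matrix(~ ., data = covariates)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    abort_bad_arg(sprintf("covariate design is rank deficient; collinear: %s.",
                          paste(bad, collapse = ", ")))
  }
  res <- qr.resid(qr_d, features)
  sweep(res, 2, colMeans(features), `+`)
}

#' Connection-wise two-sample t-tests
#'
#' Pooled-variance (Student) two-sample t-test per connection, two-sided p
#' from the t distribution with n1 + n2 - 2 degrees of freedom. The sign
#' convention matches the generator: positive t means the positive group
#' (default: second factor level, the patients) is higher. A connection with
#' zero pooled variance gets t = 0, p = 1 and is flagged.
#'
#' @param features n x P matrix.
#' @param groups Two-level factor/vector of group labels.
#' @param positive Positive-group label (default second sorted/factor level).
#' @return Tibble with `t`, `p`, `df` and `zero_variance` per connection.
#' @export
ttest_connections <- function(features, groups, positive = NULL) {
  features <- as.matrix(features)
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort_bad_arg("groups must have two levels.")
  positive <- positive %||% levels(groups)[2]
  g1 <- features[groups == positive, , drop = FALSE]
  g2 <- features[groups != positive, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 2 || n2 < 2) abort_bad_arg("each group needs >= 2 subjects.")
  v1 <- matrixStats_colVars(g1)
  v2 <- matrixStats_colVars(g2)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- colMeans(g1) - colMeans(g2)
  zero <- se == 0
  t <- ifelse(zero, 0, diff / ifelse(zero, 1, se))
  df <- n1 + n2 - 2
  p <- ifelse(zero, 1, 2 * stats::pt(-abs(t), df))
  tibble::tibble(connection = colnames(features) %||%
                   as.character(seq_along(t)),
                 t = t, p = p, df = df, zero_variance = zero)
}

# Column variances without a matrixStats dependency.
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control: the adjusted q-value of the i-th smallest p is
#' `min over j >= i of (m * p_(j) / j)`, capped at 1 (monotone, q >= p).
#' A connection is rejected when its q-value is at most `q`.
#'
#' @param p Vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return Tibble with `p`, `q_value` and `significant`.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(tibble::tibble(p = numeric(0), q_value = numeric(0),
                          significant = logical(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_bad_arg("p-values must be in [0, 1].")
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q_value <- numeric(m)
  q_value[o] <- adj_sorted
  q_value <- pmax(q_value, p)  # q >= p holds mathematically; guard rounding
  tibble::tibble(p = p, q_value = q_value, significant = q_value <= q)
}

#' Connection-wise Cohen's d
#'
#' Standardized mean difference `(mean_pos - mean_neg) / pooled SD` per
#' connection; the positive group defaults to the patients (second factor
#' level), so positive d means patients higher — matching the generator's
#' planted sign convention. Zero pooled SD yields `NA` with a warning.
#'
#' @inheritParams ttest_connections
#' @return Numeric vector of d values (one per connection).
#' @export
cohens_d_connections <- function(features, groups, positive = NULL) {
  features <- as.matrix(features)
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort_bad_arg("groups must have two levels.")
  positive <- positive %||% levels(groups)[2]
  g1 <- features[groups == positive, , drop = FALSE]
  g2 <- features[groups != positive, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 2 || n2 < 2) abort_bad_arg("each group needs >= 2 subjects.")
  sp <- sqrt(((n1 - 1) * matrixStats_colVars(g1) +
              (n2 - 1) * matrixStats_colVars(g2)) / (n1 + n2 - 2))
  zero <- sp == 0
  if (any(zero)) warning("zero pooled SD at some connections; d set to NA.",
                         call. = FALSE)
  d <- (colMeans(g1) - colMeans(g2)) / ifelse(zero, NA_real_, sp)
  d
}

#' Lightweight location-scale site harmonization
#'
#' A simplified ComBat-style harmonization, per connection: protected
#' covariate effects are fitted jointly with site effects by OLS; each
#' site's additive offset and residual scale are then removed (offsets
#' recentred to a weighted zero mean, scales rescaled to the pooled SD).
#' Optional empirical-Bayes-style shrinkage pulls the per-connection site
#' parameters toward their across-connection site means. This is a
#' simplified variant for simulation work, not a reference implementation.
#'
#' @param features n x P matrix.
#' @param site Site id per subject; every site needs >= 2 subjects.
#' @param covariates Optional data frame of covariates to preserve.
#' @param eb Apply shrinkage of site parameters (default `FALSE`).
#' @return Harmonized n x P matrix.
#' @export
combat_lite <- function(features, site, covariates = NULL, eb = FALSE) {
  features <- as.matrix(features)
  site <- factor(site)
  if (any(table(site) < 2)) abort_bad_arg("every site needs >= 2 subjects.")
  if (nlevels(site) < 2) return(features)
  n <- nrow(features)
  n_s <- as.vector(table(site))

  if (is.null(covariates)) {
    design <- matrix(1, n, 1)
  } else {
    covariates <- as.data.frame(covariates, stringsAsFactors = TRUE)
    design <- stats::model.matrix(~ ., data = covariates)
  }
  s_mat <- stats::model.matrix(~ site - 1)
  full <- cbind(design, s_mat[, -1, drop = FALSE])
  qr_f <- qr(full)
  if (qr_f$rank < ncol(full)) {
    abort_bad_arg("covariates are confounded with site; cannot harmonize.")
  }
  beta <- qr.coef(qr_f, features)
  gamma <- rbind(0, beta[(ncol(design) + 1):ncol(full), , drop = FALSE])
  # recentre site offsets to a sample-size-weighted zero mean
  gamma <- sweep(gamma, 2, colSums(gamma * n_s) / n)
  fitted <- full %*% beta
  resid <- features - fitted
  delta <- t(vapply(levels(site), function(s) {
    apply(resid[site == s, , drop = FALSE], 2, stats::sd)
  }, numeric(ncol(features))))
  pooled_sd <- sqrt(colSums(sweep(delta^2, 1, n_s - 1, `*`)) / (n - nlevels(site)))

  if (eb) {
    for (si in seq_len(nlevels(site))) {
      g <- gamma[si, ]
      tau2 <- max(stats::var(g) - mean(delta[si, ]^2) / n_s[si], 0)
      w <- if (tau2 == 0) 0 else tau2 / (tau2 + delta[si, ]^2 / n_s[si])
      gamma[si, ] <- w * g + (1 - w) * mean(g)
      delta[si, ] <- sqrt(w * delta[si, ]^2 + (1 - w) * mean(delta[si, ]^2))
    }
  }
  delta[delta == 0] <- 1

  out <- features
  for (si in seq_len(nlevels(site))) {
    rows <- site == levels(site)[si]
    base <- fitted[rows, , drop = FALSE] -
      matrix(gamma[si, ], sum(rows), ncol(features), byrow = TRUE)
    scaled <- sweep(features[rows, , drop = FALSE] - base -
                      matrix(gamma[si, ], sum(rows), ncol(features), byrow = TRUE),
                    2, delta[si, ], `/`)
    out[rows, ] <- base + sweep(scaled, 2, pooled_sd, `*`)
  }
  out
}

#' Per-region counts of significant connections
#'
#' For every region, counts the significant connections incident to it,
#' split by the sign of the effect (increased: d > 0, i.e. patients higher;
#' decreased: d < 0).
#'
#' @param significant Logical vector over the P connections (documented
#'   upper-triangle pair order).
#' @param d Cohen's d vector over the same connections.
#' @param n_regions Number of regions R (P = R(R-1)/2).
#' @param labels Optional region labels.
#' @return Tibble with `region`, `label`, `n_increased`, `n_decreased`.
#' @export
region_degree_summary <- function(significant, d, n_regions, labels = NULL) {
  pairs <- upper_pairs(n_regions)
  if (length(significant) != nrow(pairs) || length(d) != nrow(pairs)) {
    abort_bad_arg("significant/d must have length R(R-1)/2.")
  }
  labels <- labels %||% region_labels(n_regions)
  up <- significant & !is.na(d) & d > 0
  dn <- significant & !is.na(d) & d < 0
  inc <- tabulate(c(pairs$i[up], pairs$j[up]), nbins = n_regions)
  dec <- tabulate(c(pairs$i[dn], pairs$j[dn]), nbins = n_regions)
  tibble::tibble(region = seq_len(n_regions), label = labels,
                 n_increased = inc, n_decreased = dec)
}

#' Mass-univariate connection-wise analysis of a cohort
#'
#' The full univariate stage: residualize the FC features on nuisance
#' covariates (sex, age, site, mean framewise displacement by default),
#' two-sample pooled t-test per connection, Benjamini-Hochberg FDR, Cohen's
#' d, and per-region significant-connection counts.
#'
#' @param cohort An `fc_cohort`.
#' @param contrast Contrast defining the two groups (default `"mdd_vs_hc"`).
#' @param covariates Character vector of manifest columns to residualize on
#'   (default `c("sex", "age", "site", "mean_fd")`); `NULL` to skip.
#' @param q FDR level (default 0.05).
#' @param harmonize Apply [combat_lite()] site harmonization first?
#' @return A `univariate_result`: per-connection tibble `table` (regions, t,
#'   p, q_value, d, significant) and per-region `degrees`.
#' @export
univariate_connections <- function(cohort, contrast = "mdd_vs_hc",
                                   covariates = c("sex", "age", "site", "mean_fd"),
                                   q = 0.05, harmonize = FALSE) {
  stopifnot(inherits(cohort, "fc_cohort"))
  labels <- contrast_labels(contrast, cohort$manifest)
  keep <- which(!is.na(labels))
  x <- fc_features(cohort)[keep, , drop = FALSE]
  groups <- droplevels(labels[keep])
  if (harmonize) {
    cov_df <- cohort$manifest[keep, setdiff(covariates, "site"), drop = FALSE]
    x <- combat_lite(x, cohort$manifest$site[keep], covariates = cov_df)
  }
  if (!is.null(covariates)) {
    usable <- covariates[vapply(covariates, function(cv) {
      length(unique(cohort$manifest[[cv]][keep])) > 1
    }, logical(1))]
    if (length(usable)) {
      x <- residualize(x, cohort$manifest[keep, usable, drop = FALSE])
    }
  }
  tt <- ttest_connections(x, groups)
  fdr <- fdr_bh(tt$p, q = q)
  d <- cohens_d_connections(x, groups)
  r <- length(cohort$region_labels)
  pairs <- upper_pairs(r)
  table <- tibble::tibble(
    i = pairs$i, j = pairs$j,
    region_i = cohort$region_labels[pairs$i],
    region_j = cohort$region_labels[pairs$j],
    t = tt$t, p = tt$p, q_value = fdr$q_value, d = d,
    significant = fdr$significant)
  degrees <- region_degree_summary(table$significant, table$d, r,
                                   cohort$region_labels)
  structure(list(table = table, degrees = degrees, q = q,
                 n = length(keep), contrast = if (is.character(contrast))
                   contrast else contrast$name),
            class = "univariate_result")
}

#' @export
print.univariate_result <- function(x, ...) {
  cat(sprintf(
    "<univariate_result> %s, n = %d: %d / %d significant at FDR %.2g\n",
    x$contrast, x$n, sum(x$table$significant), nrow(x$table), x$q))
  invisible(x)
}
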