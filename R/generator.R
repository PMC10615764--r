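# Multi-site synthetic FC cohort generator.
#
# Subjects are built in Fisher-z space: a shared population connectome plus
# connection-wise group shifts (parameterized directly in Cohen's d), a
# multivariate sex effect, per-site additive offsets, covariate coupling
# (age, head motion) and subject-level jitter. The configured
# between_subject_sd is the TOTAL between-subject SD of z-connectivity; the
# generator apportions it into site variance, measurement noise (1/(T-3))
# and residual jitter so that realized Cohen's d matches the planted d.

#' Generator configuration for synthetic FC cohorts
#'
#' Describes a multi-site case-control cohort with planted connection-wise
#' effects. Effects are planted in Fisher-z space and parameterized directly
#' in Cohen's d: the z shift at connection (i, j) is `d * between_subject_sd`,
#' with positive d meaning patients (MDD) higher than controls.
#'
#' @param n_regions Number of atlas regions (default 112).
#' @param n_timepoints Time-series length per subject. If `<= 0`, no time
#'   series are sampled: the measured FC is emitted directly by adding
#'   Fisher-z measurement noise of SD `1/sqrt(t_eff - 3)` to the subject's
#'   target connectivity (the analytic path; much faster, same connection-wise
#'   distribution).
#' @param n_per_group Subjects per class (MDD and HC).
#' @param n_sites Number of acquisition sites.
#' @param site_sd SD of connection-wise additive site offsets, Fisher-z units.
#' @param between_subject_sd Total between-subject SD of z-connectivity at a
#'   connection (default 0.1). Must exceed the site + measurement + covariate
#'   contributions.
#' @param planted_effects Data frame with columns `i`, `j`, `d`: case-control
#'   Cohen's d planted at connection (i, j). `NULL` for none.
#' @param hub_effect List `list(region =, d =)`: the same d planted on every
#'   connection incident to one region (a hub effect). `NULL` for none.
#' @param sex_effect List `list(n_connections =, mean_abs_d =)` describing a
#'   multivariate sex effect: `n_connections` random connections receive
#'   |d| = `mean_abs_d` with random sign (positive = male higher). `NULL`
#'   disables it.
#' @param covariate_model List `list(age =, fd =)` of Fisher-z slopes per year
#'   of (centred) age and per mm of (centred) mean framewise displacement,
#'   applied to all connections.
#' @param severity_model List `list(n_connections =, r_squared =, signal_sd =)`:
#'   patient severity (HAM-D-like, baseline 20, clamped to [0, 52]) is a linear
#'   function of the measured z-connectivity at `n_connections` random
#'   connections plus noise calibrated so the population R^2 equals
#'   `r_squared`. `NULL` disables severity.
#' @param medication_fraction Fraction of patients flagged as medicated.
#' @param t_eff Effective time-series length used for measurement noise in the
#'   analytic path (default 200).
#' @param consortium Consortium tag ("A" or "B") stamped on all subjects.
#' @param base Base-connectome structure: list with `baseline` (off-diagonal
#'   floor), `block_size` (lobe-like block width; `NULL` for none),
#'   `within_block` and `homotopic` elevations (either may be `NULL`).
#' @param seed Integer seed; fully determines the cohort.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_regions = 20, n_per_group = 10, seed = 1)
#' @export
cohort_config <- function(n_regions = 112L,
                          n_timepoints = 200L,
                          n_per_group = 100L,
                          n_sites = 4L,
                          site_sd = 0.05,
                          between_subject_sd = 0.1,
                          planted_effects = NULL,
                          hub_effect = NULL,
                          sex_effect = list(n_connections = 300L, mean_abs_d = 0.25),
                          covariate_model = list(age = -8e-4, fd = -0.05),
                          severity_model = list(n_connections = 30L, r_squared = 0.05,
                                                signal_sd = 1.5),
                          medication_fraction = 0.5,
                          t_eff = 200L,
                          consortium = "A",
                          base = NULL,
                          seed = 1L) {
  n_regions <- check_count(n_regions, "n_regions", min = 3L)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 1L)
  n_sites <- check_count(n_sites, "n_sites", min = 1L)
  site_sd <- check_number(site_sd, "site_sd", min = 0)
  between_subject_sd <- check_number(between_subject_sd, "between_subject_sd", min = 1e-6)
  medication_fraction <- check_number(medication_fraction, "medication_fraction", 0, 1)
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.null(planted_effects)) {
    planted_effects <- tibble::as_tibble(planted_effects)
    stopifnot(all(c("i", "j", "d") %in% names(planted_effects)))
    if (any(abs(planted_effects$d) > 2)) {
      abort_bad_arg("planted |d| must be <= 2.")
    }
    if (any(planted_effects$i == planted_effects$j) ||
        any(planted_effects$i < 1) || any(planted_effects$j > n_regions)) {
      abort_bad_arg("planted_effects indices must be distinct regions in range.")
    }
  }
  if (!is.null(hub_effect)) {
    stopifnot(is.list(hub_effect), !is.null(hub_effect$region), !is.null(hub_effect$d))
    if (abs(hub_effect$d) > 2) abort_bad_arg("hub |d| must be <= 2.")
  }
  if (is.null(base)) {
    base <- list(baseline = 0.1,
                 block_size = if (n_regions >= 14) 14L else NULL,
                 within_block = 0.25,
                 homotopic = 0.35)
  }
  structure(
    list(n_regions = n_regions, n_timepoints = as.integer(n_timepoints),
         n_per_group = n_per_group, n_sites = n_sites, site_sd = site_sd,
         between_subject_sd = between_subject_sd,
         planted_effects = planted_effects, hub_effect = hub_effect,
         sex_effect = sex_effect, covariate_model = covariate_model,
         severity_model = severity_model,
         medication_fraction = medication_fraction, t_eff = as.integer(t_eff),
         consortium = consortium, base = base, seed = seed),
    class = "cohort_config")
}

#' Population mean connectome
#'
#' Builds the population mean correlation matrix used as the base of every
#' synthetic subject: a constant off-diagonal floor, lobe-like blocks of
#' elevated correlation, and elevated homotopic (left/right counterpart)
#' pairs under the interleaved pairing convention. The result is projected to
#' the nearest correlation matrix if the raw construction is not positive
#' semidefinite, and is guaranteed PSD on return.
#'
#' @param config A [cohort_config()].
#' @return R x R symmetric PSD matrix with unit diagonal.
#' @examples
#' b <- make_base_connectome(cohort_config(n_regions = 8, n_per_group = 4))
#' @export
make_base_connectome <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  r <- config$n_regions
  b <- config$base
  m <- matrix(b$baseline %||% 0.1, r, r)
  if (!is.null(b$block_size)) {
    blocks <- split(seq_len(r), ceiling(seq_len(r) / b$block_size))
    for (idx in blocks) m[idx, idx] <- b$within_block %||% 0.25
  }
  if (!is.null(b$homotopic)) {
    partner <- homotopic_partner(r)
    for (k in seq_len(r)) {
      if (!is.na(partner[k])) m[k, partner[k]] <- b$homotopic
    }
  }
  diag(m) <- 1
  m <- symmetrize(m)
  if (min_eigenvalue(m) < -1e-10) {
    m <- nearest_correlation(m)
  }
  if (min_eigenvalue(m) < -1e-10) {
    stop("internal error: base connectome not PSD after projection.", call. = FALSE)
  }
  dimnames(m) <- list(region_labels(r), region_labels(r))
  m
}

#' Nearest correlation matrix
#'
#' Projects a symmetric matrix onto the set of valid correlation matrices
#' (symmetric positive semidefinite, unit diagonal) in Frobenius norm, using
#' alternating projections with Dykstra's correction (Higham's method). An
#' optional eigenvalue floor returns a strictly positive definite matrix.
#'
#' @param m Square symmetric matrix.
#' @param tol Convergence tolerance on the max absolute change per sweep.
#' @param max_iter Iteration cap.
#' @param eig_floor Smallest admissible eigenvalue (default 0).
#' @return The nearest correlation matrix.
#' @examples
#' nearest_correlation(matrix(c(1, 1.2, 1.2, 1), 2, 2))
#' @export
nearest_correlation <- function(m, tol = 1e-8, max_iter = 500L, eig_floor = 0) {
  if (!is_square_matrix(m)) abort_bad_arg("`m` must be a square matrix.")
  if (max(abs(m - t(m))) > 1e-8) abort_bad_arg("`m` must be symmetric.")
  m <- symmetrize(m)
  y <- m
  ds <- matrix(0, nrow(m), ncol(m))
  for (iter in seq_len(max_iter)) {
    y_prev <- y
    r_k <- y - ds
    e <- eigen(symmetrize(r_k), symmetric = TRUE)
    vals <- pmax(e$values, eig_floor)
    x_k <- e$vectors %*% (vals * t(e$vectors))
    x_k <- symmetrize(x_k)
    ds <- x_k - r_k
    y <- x_k
    diag(y) <- 1
    if (max(abs(y - y_prev)) < tol) {
      y <- symmetrize(y)
      diag(y) <- 1
      return(y)
    }
  }
  stop(sprintf(
    "nearest_correlation did not converge in %d iterations (residual %.3g).",
    max_iter, max(abs(y - y_prev))), call. = FALSE)
}

# Precomputed cohort-level structures shared by all subjects. Draws the site
# offsets and the random connection sets from the current RNG stream.
build_cohort_context <- function(config) {
  r <- config$n_regions
  pairs <- upper_pairs(r)
  p <- nrow(pairs)
  s_total <- config$between_subject_sd

  base_r <- make_base_connectome(config)
  base_z <- fisher_z(vectorize_upper(base_r))

  # measurement noise in z units
  t_eff <- if (config$n_timepoints > 0) config$n_timepoints else config$t_eff
  if (t_eff <= 3) abort_bad_arg("effective time-series length must exceed 3.")
  meas_var <- 1 / (t_eff - 3)

  # covariate coupling (applied to every connection)
  age_mean <- 40; age_sd <- 12
  fd_shape <- 9; fd_scale <- 1 / 60   # mean 0.15 mm, sd 0.05 mm
  cm <- config$covariate_model %||% list(age = 0, fd = 0)
  beta_age <- cm$age %||% 0
  beta_fd <- cm$fd %||% 0
  cov_var <- beta_age^2 * age_sd^2 + beta_fd^2 * (fd_shape * fd_scale^2)

  # within-cohort variance contributed by k site offsets is (1 - 1/k) *
  # site_sd^2 in expectation (deviations from the cohort mean), so apportion
  # with the finite-site-count correction to keep the total SD at s.
  site_var_eff <- config$site_sd^2 * (1 - 1 / config$n_sites)
  jitter_var <- s_total^2 - site_var_eff - meas_var - cov_var
  if (jitter_var <= 1e-8) {
    abort_bad_arg(paste0(
      "between_subject_sd^2 must exceed site_sd^2 + 1/(t_eff - 3) + covariate ",
      sprintf("variance (apportioned jitter variance is %.3g).", jitter_var)))
  }

  # case-control z shift per connection (positive d: MDD > HC)
  effect_d <- numeric(p)
  key <- (pairs$i - 1) * r + pairs$j
  if (!is.null(config$planted_effects)) {
    pe <- config$planted_effects
    ii <- pmin(pe$i, pe$j); jj <- pmax(pe$i, pe$j)
    effect_d[match((ii - 1) * r + jj, key)] <- pe$d
  }
  if (!is.null(config$hub_effect)) {
    hub <- config$hub_effect$region
    effect_d[pairs$i == hub | pairs$j == hub] <- config$hub_effect$d
  }
  effect_dz <- effect_d * s_total

  # sex effect (positive: male > female)
  sex_dz <- numeric(p)
  if (!is.null(config$sex_effect)) {
    k <- min(config$sex_effect$n_connections %||% 300L, p)
    idx <- sample.int(p, k)
    sex_dz[idx] <- sample(c(-1, 1), k, replace = TRUE) *
      (config$sex_effect$mean_abs_d %||% 0.25) * s_total
  }

  # per-site additive z offsets, one draw per site per connection
  site_ids <- sprintf("site%02d", seq_len(config$n_sites))
  site_offsets <- lapply(site_ids, function(s) rnorm(p, 0, config$site_sd))
  names(site_offsets) <- site_ids

  # severity model on measured z-connectivity
  sev <- NULL
  if (!is.null(config$severity_model)) {
    k <- min(config$severity_model$n_connections %||% 30L, p)
    sig_sd <- config$severity_model$signal_sd %||% 1.5
    r2 <- config$severity_model$r_squared %||% 0.05
    idx <- sample.int(p, k)
    gamma <- rep(sig_sd / (sqrt(k) * s_total), k)
    sev <- list(idx = idx, gamma = gamma,
                eps_sd = sig_sd * sqrt((1 - r2) / r2), baseline = 20)
  }

  list(pairs = pairs, p = p, base_r = base_r, base_z = base_z,
       effect_dz = effect_dz, sex_dz = sex_dz, site_offsets = site_offsets,
       site_ids = site_ids, jitter_sd = sqrt(jitter_var),
       meas_sd = sqrt(meas_var), beta_age = beta_age, beta_fd = beta_fd,
       age_mean = age_mean, age_sd = age_sd, fd_shape = fd_shape,
       fd_scale = fd_scale, severity = sev)
}

#' Sample one synthetic subject
#'
#' Draws a single subject from the generator: target connectivity built in
#' Fisher-z space (base + group shift + sex shift + site offset + covariate
#' coupling + subject jitter), then either (a) `n_timepoints` independent
#' R-variate samples with that correlation (projected to the nearest positive
#' definite correlation first) from which the empirical FC is computed, or
#' (b) for `n_timepoints <= 0`, the measured FC obtained by adding Fisher-z
#' noise of SD `1/sqrt(t_eff - 3)` directly. Uses the current RNG stream.
#'
#' @param config A [cohort_config()].
#' @param diagnosis `"MDD"` or `"HC"`.
#' @param sex `"M"` or `"F"`.
#' @param site Site id (one of the config's site ids).
#' @param context Internal cohort context; rebuilt from `config` when `NULL`.
#' @return A list with fields `fc`, `timeseries` (or `NULL`), `age`,
#'   `mean_fd`, `severity` (patients only) and the passed phenotypes.
#' @export
sample_subject <- function(config, diagnosis = c("MDD", "HC"),
                           sex = c("M", "F"), site = NULL, context = NULL) {
  diagnosis <- match.arg(diagnosis)
  sex <- match.arg(sex)
  if (is.null(context)) context <- build_cohort_context(config)
  if (is.null(site)) site <- context$site_ids[1L]
  stopifnot(site %in% context$site_ids)
  r <- config$n_regions

  age <- min(max(rnorm(1, context$age_mean, context$age_sd), 18), 70)
  fd <- rgamma(1, shape = context$fd_shape, scale = context$fd_scale)

  g_sign <- if (diagnosis == "MDD") 0.5 else -0.5
  s_sign <- if (sex == "M") 0.5 else -0.5
  z <- context$base_z +
    g_sign * context$effect_dz +
    s_sign * context$sex_dz +
    context$site_offsets[[site]] +
    context$beta_age * (age - context$age_mean) +
    context$beta_fd * (fd - context$fd_shape * context$fd_scale) +
    rnorm(context$p, 0, context$jitter_sd)

  ts <- NULL
  if (config$n_timepoints > 0) {
    target <- devectorize_upper(inv_fisher_z(z), diag_value = 1)
    if (min_eigenvalue(target) < 1e-8) {
      target <- nearest_correlation(target, eig_floor = 1e-6)
    }
    ch <- tryCatch(chol(target), error = function(e) {
      stop("degenerate (rank-deficient) subject correlation matrix.", call. = FALSE)
    })
    ts <- matrix(rnorm(config$n_timepoints * r), config$n_timepoints, r) %*% ch
    colnames(ts) <- region_labels(r)
    fc <- pearson_fc(ts)
    z_obs <- fisher_z(vectorize_upper(fc))
  } else {
    z_obs <- z + rnorm(context$p, 0, context$meas_sd)
    fc <- devectorize_upper(inv_fisher_z(z_obs), diag_value = 1)
    dimnames(fc) <- list(region_labels(r), region_labels(r))
  }

  severity <- NA_real_
  if (diagnosis == "MDD" && !is.null(context$severity)) {
    sv <- context$severity
    severity <- sv$baseline +
      sum(sv$gamma * (z_obs[sv$idx] - context$base_z[sv$idx])) +
      rnorm(1, 0, sv$eps_sd)
    severity <- min(max(severity, 0), 52)
  }

  list(diagnosis = diagnosis, sex = sex, site = site, age = age,
       mean_fd = fd, severity = severity, fc = fc, timeseries = ts)
}

#' Generate a multi-site case-control cohort
#'
#' Draws `2 * n_per_group` subjects (balanced MDD/HC), assigns sexes roughly
#' 60/40 M/F, spreads each class over the sites in balanced shuffled
#' round-robin fashion, flags a configured fraction of patients as medicated,
#' and samples each subject's connectivity via [sample_subject()]. The output
#' is fully determined by `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An `fc_cohort`: list with a `manifest` tibble (subject_id,
#'   diagnosis, sex, age, site, consortium, medicated, mean_fd, severity),
#'   a named list `fc` of R x R matrices, optional `timeseries`,
#'   `region_labels` and the `config`.
#' @examples
#' co <- generate_cohort(cohort_config(n_regions = 10, n_per_group = 6,
#'                                     n_sites = 2, n_timepoints = 0, seed = 1))
#' co$manifest
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_per_group < config$n_sites) {
    abort_bad_arg("n_per_group must be >= n_sites so every site is populated.")
  }
  set.seed(config$seed)
  context <- build_cohort_context(config)
  n <- config$n_per_group

  per_group <- function(diagnosis) {
    n_m <- round(0.6 * n)
    sexes <- sample(c(rep("M", n_m), rep("F", n - n_m)))
    sites <- sample(rep_len(context$site_ids, n))
    list(diagnosis = rep(diagnosis, n), sex = sexes, site = sites)
  }
  gm <- per_group("MDD")
  gh <- per_group("HC")
  diagnosis <- c(gm$diagnosis, gh$diagnosis)
  sex <- c(gm$sex, gh$sex)
  site <- c(gm$site, gh$site)
  medicated <- ifelse(diagnosis == "MDD",
                      runif(2 * n) < config$medication_fraction, NA)

  subjects <- vector("list", 2 * n)
  for (s in seq_len(2 * n)) {
    subjects[[s]] <- sample_subject(config, diagnosis[s], sex[s], site[s],
                                    context = context)
  }
  ids <- sprintf("S%04d", seq_len(2 * n))
  manifest <- tibble::tibble(
    subject_id = ids,
    diagnosis = diagnosis,
    sex = sex,
    age = vapply(subjects, `[[`, numeric(1), "age"),
    site = site,
    consortium = config$consortium,
    medicated = medicated,
    mean_fd = vapply(subjects, `[[`, numeric(1), "mean_fd"),
    severity = vapply(subjects, `[[`, numeric(1), "severity"))

  fc <- lapply(subjects, `[[`, "fc")
  names(fc) <- ids
  ts <- NULL
  if (config$n_timepoints > 0) {
    ts <- lapply(subjects, `[[`, "timeseries")
    names(ts) <- ids
  }
  new_fc_cohort(manifest, fc, region_labels(config$n_regions),
                timeseries = ts, config = config, base = context$base_r)
}

#' Construct an FC cohort from existing data
#'
#' Wraps a phenotype manifest and a list of FC matrices (e.g. read from disk
#' or computed from time series) into the cohort container the classification
#' and statistics stages consume.
#'
#' @param manifest Data frame with at least `subject_id`, `diagnosis`, `sex`,
#'   `age`, `site`; optionally `consortium`, `medicated`, `mean_fd`,
#'   `severity`.
#' @param fc Named list of R x R connectivity matrices (names = subject ids).
#' @param region_labels Character vector of region names.
#' @param timeseries Optional named list of T x R matrices.
#' @param config Optional generator config (for synthetic cohorts).
#' @param base Optional population mean connectome.
#' @return An `fc_cohort` object.
#' @export
new_fc_cohort <- function(manifest, fc, region_labels,
                          timeseries = NULL, config = NULL, base = NULL) {
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("subject_id", "diagnosis", "sex", "age", "site") %in% names(manifest)),
            is.list(fc), length(fc) == nrow(manifest))
  if (is.null(names(fc))) names(fc) <- manifest$subject_id
  if (!all(manifest$subject_id %in% names(fc))) {
    abort_bad_arg("every manifest subject needs an FC matrix.")
  }
  r <- length(region_labels)
  for (id in manifest$subject_id) validate_fc(fc[[id]], n_regions = r)
  structure(list(manifest = manifest, fc = fc[manifest$subject_id],
                 timeseries = timeseries, region_labels = region_labels,
                 config = config, base = base),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<fc_cohort> %d subjects x %d regions, %d site(s)\n",
              nrow(m), length(x$region_labels), length(unique(m$site))))
  print(dplyr::count(m, .data$diagnosis, .data$sex))
  invisible(x)
}

# Subset a cohort by manifest row index, keeping manifest/fc/timeseries aligned.
subset_cohort <- function(cohort, idx) {
  ids <- cohort$manifest$subject_id[idx]
  new_fc_cohort(cohort$manifest[idx, , drop = FALSE], cohort$fc[ids],
                cohort$region_labels,
                timeseries = if (!is.null(cohort$timeseries)) cohort$timeseries[ids],
                config = cohort$config, base = cohort$base)
}
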