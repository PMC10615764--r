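# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort_bad_arg(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort_bad_arg(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  as.numeric(x)
}

#' Fisher z-transform of correlations
#'
#' `fisher_z()` maps correlations to `atanh(r)` (clamping away from +/-1 so the
#' transform stays finite); `inv_fisher_z()` maps back with `tanh()`.
#'
#' @param r Numeric vector or matrix of correlations.
#' @param z Numeric vector or matrix of Fisher-z values.
#' @return Numeric object of the same shape.
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  atanh(r)
}

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Upper-triangle pair index table
#'
#' The (i, j) region pairs, i < j, in the row-major lexicographic order used
#' by [vectorize_upper()] and by every connection-wise result table: (1,2),
#' (1,3), ..., (1,R), (2,3), ..., (R-1,R).
#'
#' @param n_regions Number of regions R.
#' @return Tibble with integer columns `i` and `j` (R(R-1)/2 rows).
#' @examples
#' upper_pairs(4)
#' @export
upper_pairs <- function(n_regions) {
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(a) (a + 1L):n_regions),
              use.names = FALSE)
  tibble::tibble(i = i, j = j)
}

#' Deterministic child seed for a named stage
#'
#' Derives a child seed from a master seed and a stage name, so adding a
#' stage to a pipeline never shifts another stage's random stream. The
#' result is always below 2^31.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name (character).
#' @return An integer seed.
#' @examples
#' child_seed(1, "simulate_cohort1")
#' @export
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Symmetrize a square matrix.
symmetrize <- function(m) (m + t(m)) / 2

is_square_matrix <- function(m) is.matrix(m) && nrow(m) == ncol(m)

min_eigenvalue <- function(m) {
  min(eigen(symmetrize(m), symmetric = TRUE, only.values = TRUE)$values)
}
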