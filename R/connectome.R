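# FC construction and graph building: time series -> Pearson FC matrix ->
# upper-triangle SVM features or sparsified connectome graph.

#' Validate a connectivity matrix
#'
#' Checks the connectivity-matrix contract: square, symmetric, unit diagonal,
#' entries in [-1, 1].
#'
#' @param fc Matrix to validate.
#' @param n_regions Optional expected dimension.
#' @return `fc`, invisibly, or an error.
#' @export
validate_fc <- function(fc, n_regions = NULL) {
  if (!is_square_matrix(fc)) abort_bad_arg("FC must be a square matrix.")
  if (!is.null(n_regions) && nrow(fc) != n_regions) {
    abort_bad_arg(sprintf("FC must be %d x %d.", n_regions, n_regions))
  }
  if (max(abs(fc - t(fc))) > 1e-8) abort_bad_arg("FC must be symmetric.")
  if (max(abs(diag(fc) - 1)) > 1e-8) abort_bad_arg("FC diagonal must be 1.")
  if (max(abs(fc)) > 1 + 1e-8) abort_bad_arg("FC entries must lie in [-1, 1].")
  invisible(fc)
}

#' Pearson functional connectivity matrix
#'
#' Computes the region-by-region Pearson correlation matrix of a multivariate
#' time series; entry (i, j) is the correlation of columns i and j, and the
#' diagonal is set to exactly 1.
#'
#' @param timeseries T x R numeric matrix (rows = timepoints).
#' @param labels Optional region labels (defaults to column names).
#' @return R x R connectivity matrix.
#' @examples
#' ts <- matrix(rnorm(40), 10, 4)
#' pearson_fc(ts)
#' @export
pearson_fc <- function(timeseries, labels = NULL) {
  if (!is.matrix(timeseries)) timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3) abort_bad_arg("need at least 3 timepoints.")
  labels <- labels %||% colnames(timeseries) %||%
    sprintf("R%03d", seq_len(ncol(timeseries)))
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    abort_bad_arg(sprintf("constant time series in region(s): %s.",
                          paste(labels[sds == 0], collapse = ", ")))
  }
  fc <- stats::cor(timeseries)
  diag(fc) <- 1
  fc <- symmetrize(fc)
  dimnames(fc) <- list(labels, labels)
  fc
}

#' Vectorize the upper triangle of an FC matrix
#'
#' Extracts the strictly-upper-triangular entries in row-major pair order:
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R) — i.e. pairs (i, j), i < j,
#' sorted lexicographically. This is the fixed feature order used for SVM
#' inputs and all connection-wise statistics. `devectorize_upper()` inverts it.
#'
#' @param fc R x R symmetric matrix.
#' @return Numeric vector of length R(R-1)/2.
#' @examples
#' m <- diag(3); m[1, 2] <- m[2, 1] <- .5
#' vectorize_upper(m)
#' @export
vectorize_upper <- function(fc) {
  if (!is_square_matrix(fc)) abort_bad_arg("`fc` must be a square matrix.")
  tm <- t(fc)
  tm[lower.tri(tm)]
}

#' @rdname vectorize_upper
#' @param v Vector of length R(R-1)/2 in the documented pair order.
#' @param diag_value Value for the reconstructed diagonal (default 1).
#' @export
devectorize_upper <- function(v, diag_value = 1) {
  r <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(r - round(r)) > 1e-9) abort_bad_arg("length(v) is not R(R-1)/2.")
  r <- as.integer(round(r))
  m <- matrix(0, r, r)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Binarize an FC matrix by top-K absolute correlation
#'
#' Ranks the P = R(R-1)/2 distinct connections by absolute correlation,
#' descending, and keeps exactly `K = ceiling(sparsity * P)` edges; ties at
#' the cutoff are broken by lexicographic pair order (the smaller (i, j)
#' wins). Returns the symmetric binary adjacency with zero diagonal.
#'
#' @param fc R x R connectivity matrix.
#' @param sparsity Fraction of connections to keep, in (0, 1) (default 0.5,
#'   the top half of connections).
#' @return R x R binary adjacency matrix.
#' @examples
#' fc <- devectorize_upper(c(.9, .5, .1))
#' binarize_topk(fc, 0.5)
#' @export
binarize_topk <- function(fc, sparsity = 0.5) {
  if (!is_square_matrix(fc)) abort_bad_arg("`fc` must be a square matrix.")
  if (!(sparsity > 0 && sparsity < 1)) abort_bad_arg("`sparsity` must be in (0, 1).")
  r <- nrow(fc)
  pairs <- upper_pairs(r)
  v <- vectorize_upper(fc)
  k <- ceiling(sparsity * length(v))
  # stable radix sort: ties keep the vector's (i, j) lexicographic order
  ord <- order(-abs(v), method = "radix")
  keep <- ord[seq_len(k)]
  adj <- matrix(0, r, r)
  ij <- cbind(pairs$i[keep], pairs$j[keep])
  adj[ij] <- 1
  adj[ij[, 2:1, drop = FALSE]] <- 1
  dimnames(adj) <- dimnames(fc)
  adj
}

#' Build a connectome graph from an FC matrix
#'
#' A graph has a binary adjacency (the top-`sparsity` fraction of connections
#' by absolute correlation, see [binarize_topk()]) and node features: row i of
#' the node-feature matrix is the region's full connectivity profile — its FC
#' row before binarization, with the self-correlation zeroed.
#'
#' @param fc R x R connectivity matrix.
#' @param sparsity Edge fraction kept (default 0.5).
#' @param labels Optional region labels.
#' @return A `connectome_graph`: list with `adjacency`, `node_features`,
#'   `region_labels`.
#' @export
build_graph <- function(fc, sparsity = 0.5, labels = NULL) {
  labels <- labels %||% rownames(fc) %||% sprintf("R%03d", seq_len(nrow(fc)))
  adj <- binarize_topk(fc, sparsity)
  feats <- fc
  diag(feats) <- 0
  structure(list(adjacency = adj, node_features = feats,
                 region_labels = labels),
            class = "connectome_graph")
}

#' Symmetric GCN propagation matrix
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `D` is the degree matrix of
#' `A + I`: the standard renormalized propagation operator for graph
#' convolution. Self-loops guarantee positive degrees, so isolated nodes get
#' a diagonal entry of 1.
#'
#' @param adjacency Binary symmetric adjacency matrix with zero diagonal.
#' @return R x R symmetric propagation matrix.
#' @examples
#' a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 1
#' normalize_adjacency(a)
#' @export
normalize_adjacency <- function(adjacency) {
  if (!is_square_matrix(adjacency)) abort_bad_arg("adjacency must be square.")
  a <- adjacency
  diag(a) <- 0
  a_tilde <- a + diag(nrow(a))
  d_inv_sqrt <- 1 / sqrt(rowSums(a_tilde))
  symmetrize(a_tilde * outer(d_inv_sqrt, d_inv_sqrt))
}

#' Subject-by-connection feature matrix of a cohort
#'
#' Stacks each subject's vectorized FC upper triangle (documented pair order)
#' into an n x P matrix — the SVM feature representation and the input of the
#' connection-wise statistics.
#'
#' @param cohort An `fc_cohort`.
#' @param fisher Transform features to Fisher z before stacking? Default
#'   `FALSE` (raw correlations are fed to the classifiers).
#' @return n x R(R-1)/2 matrix with subject ids as row names and
#'   "region_i|region_j" column names.
#' @export
fc_features <- function(cohort, fisher = FALSE) {
  stopifnot(inherits(cohort, "fc_cohort"))
  x <- t(vapply(cohort$fc, vectorize_upper,
                numeric(length(cohort$fc[[1]][upper.tri(cohort$fc[[1]])]))))
  rownames(x) <- cohort$manifest$subject_id
  pairs <- upper_pairs(length(cohort$region_labels))
  colnames(x) <- paste(cohort$region_labels[pairs$i],
                       cohort$region_labels[pairs$j], sep = "|")
  if (fisher) x <- fisher_z(x)
  x
}

#' Build graphs for every subject of a cohort
#'
#' @param cohort An `fc_cohort`.
#' @param sparsity Edge fraction kept per subject (default 0.5).
#' @return Named list of `connectome_graph` objects.
#' @export
cohort_graphs <- function(cohort, sparsity = 0.5) {
  stopifnot(inherits(cohort, "fc_cohort"))
  lapply(cohort$fc, build_graph, sparsity = sparsity,
         labels = cohort$region_labels)
}

#' Zero out the connectivity profile of regions
#'
#' Removes all information carried by the given regions from an FC matrix by
#' zeroing their rows AND columns (both zeroed to preserve symmetry); the
#' diagonal stays 1. Used by the ablation study before graph reconstruction.
#'
#' @param fc R x R connectivity matrix.
#' @param regions Integer vector of region indices.
#' @return The masked FC matrix.
#' @export
mask_region_fc <- function(fc, regions) {
  stopifnot(all(regions >= 1), all(regions <= nrow(fc)))
  fc[regions, ] <- 0
  fc[, regions] <- 0
  diag(fc) <- 1
  fc
}
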