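# Plain-text interchange: TSV manifests, FC matrices and time series, YAML
# configs, TSV attribution/univariate tables.

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write and read FC matrices as TSV
#'
#' An FC matrix is stored as an R x R tab-separated table with region labels
#' as the header (no row names).
#'
#' @param fc R x R connectivity matrix.
#' @param path File path.
#' @return `read_fc_matrix()` returns the matrix.
#' @export
write_fc_matrix <- function(fc, path) {
  utils::write.table(fc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  dimnames(m) <- list(colnames(m), colnames(m))
  m
}

#' Write a cohort to a directory
#'
#' Writes the phenotype manifest (`manifest.tsv`), one FC TSV per subject
#' under `fc/`, optional time-series TSVs (T rows x R labelled columns)
#' under `timeseries/`, region labels, and the generator configuration as
#' YAML when present. `read_cohort()` inverts it.
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if needed).
#' @param timeseries Also write time series when available? Default `FALSE`.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, timeseries = FALSE) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(file.path(dir, "fc"), recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain(cohort$manifest, file.path(dir, "manifest.tsv"))
  writeLines(cohort$region_labels, file.path(dir, "region_labels.txt"))
  for (id in cohort$manifest$subject_id) {
    write_fc_matrix(cohort$fc[[id]], file.path(dir, "fc", paste0(id, ".tsv")))
  }
  if (timeseries && !is.null(cohort$timeseries)) {
    dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
    for (id in cohort$manifest$subject_id) {
      write_tsv_plain(as.data.frame(cohort$timeseries[[id]]),
                      file.path(dir, "timeseries", paste0(id, ".tsv")))
    }
  }
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$planted_effects <- if (!is.null(cfg$planted_effects))
      as.list(as.data.frame(cfg$planted_effects))
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(read_tsv_plain(file.path(dir, "manifest.tsv")))
  labels <- readLines(file.path(dir, "region_labels.txt"))
  fc <- lapply(manifest$subject_id, function(id) {
    read_fc_matrix(file.path(dir, "fc", paste0(id, ".tsv")))
  })
  names(fc) <- manifest$subject_id
  new_fc_cohort(manifest, fc, labels)
}

#' Write a connectome graph as edge list plus node features
#'
#' @param graph A `connectome_graph`.
#' @param edge_path,features_path Output TSV paths.
#' @return `edge_path`, invisibly.
#' @export
write_graph_tsv <- function(graph, edge_path, features_path = NULL) {
  r <- nrow(graph$adjacency)
  pairs <- upper_pairs(r)
  keep <- graph$adjacency[cbind(pairs$i, pairs$j)] == 1
  edges <- tibble::tibble(i = pairs$i[keep], j = pairs$j[keep],
                          region_i = graph$region_labels[pairs$i[keep]],
                          region_j = graph$region_labels[pairs$j[keep]])
  write_tsv_plain(edges, edge_path)
  if (!is.null(features_path)) {
    write_tsv_plain(as.data.frame(graph$node_features), features_path)
  }
  invisible(edge_path)
}
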