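# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Per-fold metrics tibble.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    mean_balanced_accuracy = x$mean_balanced_accuracy,
    sd_balanced_accuracy = x$sd_balanced_accuracy,
    mean_f1 = mean(x$folds$f1, na.rm = TRUE),
    mean_sensitivity = mean(x$folds$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$folds$specificity, na.rm = TRUE),
    n = x$n, k = x$k,
    p_value = x$p_value, n_perms = x$n_perms)
}

#' Tidy a univariate connection-wise result
#'
#' @param x A `univariate_result`.
#' @param ... Unused.
#' @return The per-connection table (regions, t, p, q_value, d, significant).
#' @export
tidy.univariate_result <- function(x, ...) x$table

#' @rdname tidy.univariate_result
#' @export
glance.univariate_result <- function(x, ...) {
  sig <- x$table[x$table$significant, ]
  tibble::tibble(
    n = x$n, n_connections = nrow(x$table),
    n_significant = nrow(sig),
    mean_d_decreased = mean(sig$d[sig$d < 0]),
    mean_d_increased = mean(sig$d[sig$d > 0]),
    q = x$q)
}

#' Tidy an ablation result
#'
#' @param x An `ablation_result`.
#' @param ... Unused.
#' @return Per-region mean/SD accuracy-drop tibble.
#' @export
tidy.ablation_result <- function(x, ...) x$regions

#' Tidy an edge-mask explainer result
#'
#' @param x An `edge_mask_result`.
#' @param ... Unused.
#' @return Ranked top-edges tibble.
#' @export
tidy.edge_mask_result <- function(x, ...) x$top_edges

#' Tidy a severity regression result
#'
#' @param x A `severity_result`.
#' @param ... Unused.
#' @return Per-fold R^2 tibble.
#' @export
tidy.severity_result <- function(x, ...) x$folds

#' @rdname tidy.severity_result
#' @export
glance.severity_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared,
                 baseline_r_squared = x$baseline_r_squared,
                 n_patients = x$n_patients)
}

#' Plot per-fold CV metrics
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$folds[, c("fold", "balanced_accuracy", "f1", "sensitivity",
                     "specificity")],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "fold", y = "metric value",
                  title = sprintf("%s: mean balanced accuracy %.3f",
                                  object$contrast %||% object$family,
                                  object$mean_balanced_accuracy)) +
    ggplot2::ylim(0, 1)
}

#' Plot per-region significant-connection counts
#'
#' Mirrors the region-degree summary: counts of significantly increased and
#' decreased connections per region, for the regions with the largest totals.
#'
#' @param object A `univariate_result`.
#' @param top_n Number of regions shown (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.univariate_result <- function(object, top_n = 20, ...) {
  deg <- object$degrees
  deg$total <- deg$n_increased + deg$n_decreased
  deg <- utils::head(deg[order(-deg$total), ], top_n)
  df <- tidyr::pivot_longer(deg[, c("label", "n_increased", "n_decreased")],
                            -"label", names_to = "direction",
                            values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$count),
                                   y = .data$count, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "significant connections",
                  title = sprintf("Region degree summary (FDR %.2g)", object$q))
}

#' Plot region-ablation accuracy drops
#'
#' @param object An `ablation_result`.
#' @param top_n Number of regions shown (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ablation_result <- function(object, top_n = 20, ...) {
  df <- utils::head(object$regions[order(-object$regions$mean_drop), ], top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$mean_drop),
                                   y = .data$mean_drop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_drop - .data$sd_drop,
                                        ymax = .data$mean_drop + .data$sd_drop),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accuracy drop (percentage points)",
                  title = sprintf("Region ablation (%d repeats)",
                                  object$n_repeats))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
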