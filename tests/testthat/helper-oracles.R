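# Independent brute-force oracles used to cross-check the implementations.
# These deliberately use naive loops / first-principles formulas.

oracle_pearson <- function(ts) {
  r <- ncol(ts)
  out <- diag(r)
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      if (i == j) next
      xi <- ts[, i]; xj <- ts[, j]
      num <- sum((xi - mean(xi)) * (xj - mean(xj)))
      den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      out[i, j] <- num / den
    }
  }
  out
}

oracle_confusion_metrics <- function(truth, pred, positive) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (s in seq_along(truth)) {
    if (truth[s] == positive && pred[s] == positive) tp <- tp + 1
    if (truth[s] != positive && pred[s] == positive) fp <- fp + 1
    if (truth[s] != positive && pred[s] != positive) tn <- tn + 1
    if (truth[s] == positive && pred[s] != positive) fn <- fn + 1
  }
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  c(balanced_accuracy = (sens + spec) / 2,
    f1 = 2 * tp / (2 * tp + fp + fn),
    sensitivity = sens, specificity = spec)
}

oracle_cohens_d <- function(x1, x2) {
  sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
               (length(x1) + length(x2) - 2))
  (mean(x1) - mean(x2)) / sp
}

# Step-up BH by direct enumeration of the rejection rule: find the largest i
# with p_(i) <= i*q/m and reject everything at or below it.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- which(ps <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(thresh) > 0) rejected[o[seq_len(max(thresh))]] <- TRUE
  rejected
}
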