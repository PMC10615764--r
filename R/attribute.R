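# Attribution: edge-mask explainer for the GCN, region-ablation study, and
# cross-cohort consensus ranking.

# Forward/backward pass of a gcn_model for ONE subject with an explicit
# propagation matrix S and node features X (both already masked). Returns
# the gradients of the prediction loss against `target` with respect to S
# and X.
gcn_subject_grad_s <- function(model, s_mat, x, target) {
  n_layers <- model$n_layers
  r <- nrow(s_mat)
  h <- x
  inputs <- vector("list", n_layers)
  pres <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    inputs[[l]] <- h
    pre <- s_mat %*% (h %*% model$w[[l]])
    bias_l <- model$bl[[l]] %||% numeric(ncol(pre))
    pre <- sweep(pre, 2, bias_l, `+`)
    pres[[l]] <- pre
    h <- pmax(pre, 0)
  }
  pooled <- colMeans(h)
  score <- sum(pooled * model$w_out) + model$b
  p <- stats::plogis(score)
  loss <- -(target * log(max(p, 1e-12)) + (1 - target) * log(max(1 - p, 1e-12)))

  dscore <- p - target
  dh <- matrix(rep(dscore * drop(model$w_out), each = r) / r, r)
  ds <- matrix(0, r, r)
  dx <- matrix(0, r, r)
  for (l in rev(seq_len(n_layers))) {
    dpre <- dh * (pres[[l]] > 0)
    ds <- ds + dpre %*% t(inputs[[l]] %*% model$w[[l]])
    dh <- s_mat %*% dpre %*% t(model$w[[l]])
    if (l == 1L) dx <- dh
  }
  list(ds = ds, dx = dx, loss = loss, p = p)
}

#' Edge-mask explanation of a trained GCN
#'
#' Learns, per subject, a real-valued mask `M = sigmoid(theta)` in [0, 1]
#' over the R(R-1)/2 connections of the subject's connectome. During the
#' forward pass the mask gates each connection in both the (renormalized)
#' propagation matrix at the graph's edges and the node-feature matrix —
#' masked feature entries are imputed to the cohort mean profile, so masking
#' removes a connection's *information*, not just its value. The mask is
#' optimized with Adam to retain the model's own unmasked predicted class
#' (cross-entropy against that class) while being sparse: the objective adds
#' `lambda_size * mean(M)` and `lambda_ent` times the mean elementwise
#' binary entropy of M.
#'
#' Because a mask that merely preserves a prediction also retains
#' connections that carry class-independent signal (large shared
#' correlations raise the score for everyone), each subject additionally
#' contributes a control mask optimized toward the *opposite* class. The
#' edge importance used for ranking is the mean over correctly classified
#' subjects of `m_own - m_flip`: structure that is kept (or dropped)
#' regardless of the target cancels, and only class-discriminative
#' connections survive. The reported `mask` is the plain mean of the
#' own-target masks.
#'
#' @param model A classification `gcn_model`.
#' @param graphs List of `connectome_graph`s the model is explained on;
#'   held-out subjects give cleaner explanations than training subjects
#'   (on training data the mask keeps the model's memorized noise
#'   directions).
#' @param labels True class labels (used only to select correctly classified
#'   subjects for aggregation).
#' @param epochs Mask optimization epochs (default 150, per target).
#' @param lr Mask learning rate (default 0.05, Adam).
#' @param lambda_size Size penalty weight (default 0.5); the dominant
#'   sparsity pressure that drives uninformative connections to zero.
#' @param lambda_ent Entropy penalty weight (default 0.05), kept below the
#'   size penalty so it sharpens rather than saturates the mask.
#' @param top_k Number of top edges to report (default 10).
#' @param seed Seed for mask initialization.
#' @return An `edge_mask_result`: symmetric R x R `mask` in [0, 1] (zero
#'   diagonal; mean own-target mask), symmetric `importance` matrix (mean
#'   of own minus flipped-target masks, used for the ranking), `per_class`
#'   masks, ranked `top_edges` tibble, and the mean objective trace.
#' @export
explain_gcn <- function(model, graphs, labels, epochs = 150L, lr = 0.05,
                        lambda_size = 0.5, lambda_ent = 0.05, top_k = 10L,
                        seed = 1L) {
  stopifnot(inherits(model, "gcn_model"), !model$regression,
            length(graphs) == length(labels))
  if (model$n_layers < 1) abort_bad_arg("explainer needs >= 1 conv layer.")
  set.seed(seed)
  p_unmasked <- gcn_predict(model, graphs)
  cls <- as.integer(p_unmasked >= 0.5)
  pred_label <- model$levels[cls + 1L]
  correct <- which(pred_label == as.character(labels))
  if (length(correct) == 0) abort_bad_arg("no correctly classified subjects.")
  r <- nrow(graphs[[1]]$adjacency)
  pairs <- upper_pairs(r)
  np <- nrow(pairs)
  ij <- cbind(pairs$i, pairs$j)
  ji <- ij[, 2:1, drop = FALSE]
  xbar <- Reduce(`+`, lapply(graphs, `[[`, "node_features")) / length(graphs)

  optimize_mask <- function(ahat, x0, target, trace_row = NULL) {
    dev <- x0 - xbar
    theta <- rnorm(np, 0, 0.1)
    am <- numeric(np); av <- numeric(np)
    trace <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      m <- stats::plogis(theta)
      mf <- matrix(1, r, r)
      mf[ij] <- m; mf[ji] <- m
      diag(mf) <- 1            # self-loops stay unmasked
      s_mat <- ahat * mf
      x <- xbar + dev * mf
      diag(x) <- 0
      bk <- gcn_subject_grad_s(model, s_mat, x, target)
      ent <- -m * log(pmax(m, 1e-12)) - (1 - m) * log(pmax(1 - m, 1e-12))
      trace[epoch] <- bk$loss + lambda_size * mean(m) + lambda_ent * mean(ent)
      ds_a <- bk$ds * ahat
      dx_d <- bk$dx * dev
      dm <- ds_a[ij] + ds_a[ji] + dx_d[ij] + dx_d[ji]
      dm <- dm + lambda_size / np +
        lambda_ent * log((1 - m + 1e-12) / (m + 1e-12)) / np
      dtheta <- dm * m * (1 - m)
      am <- 0.9 * am + 0.1 * dtheta
      av <- 0.999 * av + 0.001 * dtheta^2
      theta <- theta - lr * (am / (1 - 0.9^epoch)) /
        (sqrt(av / (1 - 0.999^epoch)) + 1e-8)
    }
    list(m = stats::plogis(theta), trace = trace)
  }

  masks <- vector("list", length(correct))
  importances <- vector("list", length(correct))
  traces <- matrix(NA_real_, length(correct), epochs)
  for (ci in seq_along(correct)) {
    s_idx <- correct[ci]
    g <- graphs[[s_idx]]
    ahat <- normalize_adjacency(g$adjacency)
    own <- optimize_mask(ahat, g$node_features, cls[s_idx])
    flip <- optimize_mask(ahat, g$node_features, 1L - cls[s_idx])
    traces[ci, ] <- own$trace
    mk <- matrix(0, r, r)
    mk[ij] <- own$m; mk[ji] <- own$m
    masks[[ci]] <- mk
    im <- matrix(0, r, r)
    im[ij] <- own$m - flip$m; im[ji] <- own$m - flip$m
    importances[[ci]] <- im
  }

  mean_mask <- Reduce(`+`, masks) / length(masks)
  importance <- Reduce(`+`, importances) / length(importances)
  per_class <- lapply(c(0L, 1L), function(kls) {
    sel <- which(cls[correct] == kls)
    if (length(sel) == 0) return(NULL)
    Reduce(`+`, masks[sel]) / length(sel)
  })
  names(per_class) <- model$levels

  labels_r <- graphs[[1]]$region_labels %||% sprintf("R%03d", seq_len(r))
  w <- vectorize_upper(importance)
  ord <- order(-w, pairs$i, pairs$j)
  top <- ord[seq_len(min(top_k, np))]
  top_edges <- tibble::tibble(
    rank = seq_along(top), i = pairs$i[top], j = pairs$j[top],
    region_i = labels_r[pairs$i[top]], region_j = labels_r[pairs$j[top]],
    weight = w[top])

  structure(list(mask = mean_mask, importance = importance,
                 per_class = per_class,
                 top_edges = top_edges, n_used = length(correct),
                 objective_trace = colMeans(traces),
                 region_labels = labels_r),
            class = "edge_mask_result")
}

#' @export
print.edge_mask_result <- function(x, ...) {
  cat(sprintf("<edge_mask_result> aggregated over %d subjects; top edges:\n",
              x$n_used))
  print(x$top_edges)
  invisible(x)
}

#' Region-ablation importance study
#'
#' For each repeat: a fresh balanced subsample and train/test split, a fresh
#' GCN training run, and a baseline test balanced accuracy. Then, for every
#' region, the region's connectivity profile is removed from each TEST
#' subject's FC (row and column zeroed; training untouched), graphs are
#' rebuilt (top-K recomputed on the masked matrix) and the model is
#' re-evaluated; the drop in accuracy (percentage points, baseline minus
#' masked) is attributed to the region. Reports the mean and SD of the drop
#' over repeats.
#'
#' @param cohort An `fc_cohort`.
#' @param contrast Contrast (default `"mdd_vs_hc"`).
#' @param spec A [model_spec()] with a GCN family; the first grid row is used.
#' @param regions Regions to ablate (default: all).
#' @param n_repeats Independent train-test repeats (default 10).
#' @param test_fraction Held-out fraction per repeat (default 0.2).
#' @param seed Seed.
#' @return An `ablation_result`: per-region tibble (`region`, `label`,
#'   `mean_drop`, `sd_drop` in percentage points) and per-repeat baselines.
#' @export
ablate_region <- function(cohort, contrast = "mdd_vs_hc",
                          spec = model_spec("gcn"), regions = NULL,
                          n_repeats = 10L, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(cohort, "fc_cohort"), is_gcn_family(spec$family))
  r <- length(cohort$region_labels)
  regions <- regions %||% seq_len(r)
  stopifnot(all(regions >= 1), all(regions <= r))
  k_split <- max(2L, round(1 / test_fraction))
  hyper <- spec$grid[1, , drop = FALSE]

  drops <- matrix(NA_real_, n_repeats, length(regions))
  baselines <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    rs <- child_seed(seed, sprintf("rep%d", rep_i))
    sub <- subsample_balanced(cohort, contrast, rs)
    y <- contrast_labels(contrast, sub$manifest)
    folds <- make_folds(y, sub$manifest$site, k = k_split, seed = rs)
    te <- which(folds == 1L); tr <- which(folds != 1L)
    graphs_tr <- cohort_graphs(subset_cohort(sub, tr), spec$sparsity)
    model <- gcn_train(graphs_tr, y[tr],
                       hidden = hyper$hidden %||% spec$hidden,
                       n_layers = hyper$n_layers %||% spec$n_layers,
                       epochs = spec$epochs, lr = spec$lr,
                       decay_every = spec$decay_every,
                       decay_factor = spec$decay_factor,
                       dropout = spec$dropout, batch_size = spec$batch_size,
                       seed = child_seed(rs, "train"))
    fc_te <- sub$fc[sub$manifest$subject_id[te]]
    graphs_te <- lapply(fc_te, build_graph, sparsity = spec$sparsity,
                        labels = sub$region_labels)
    predict_acc <- function(graphs) {
      pred <- factor(model$levels[(gcn_predict(model, graphs) >= 0.5) + 1L],
                     levels = model$levels)
      evaluate_metrics(y[te], pred, levels(y)[2])$balanced_accuracy
    }
    baselines[rep_i] <- predict_acc(graphs_te)
    for (gi in seq_along(regions)) {
      masked <- lapply(fc_te, function(fc) {
        build_graph(mask_region_fc(fc, regions[gi]), sparsity = spec$sparsity,
                    labels = sub$region_labels)
      })
      drops[rep_i, gi] <- (baselines[rep_i] - predict_acc(masked)) * 100
    }
  }

  structure(list(
    regions = tibble::tibble(
      region = regions,
      label = cohort$region_labels[regions],
      mean_drop = colMeans(drops),
      sd_drop = apply(drops, 2, stats::sd)),
    baselines = tibble::tibble(repeat_id = seq_len(n_repeats),
                               balanced_accuracy = baselines),
    n_repeats = n_repeats, region_labels = cohort$region_labels),
    class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("<ablation_result> %d regions x %d repeats; largest drops:\n",
              nrow(x$regions), x$n_repeats))
  print(utils::head(dplyr::arrange(x$regions, dplyr::desc(.data$mean_drop)), 5))
  invisible(x)
}

ranked_ids <- function(x, top_k) {
  if (inherits(x, "ablation_result")) {
    tb <- dplyr::arrange(x$regions, dplyr::desc(.data$mean_drop),
                         .data$region)
    utils::head(tb$label, top_k)
  } else if (inherits(x, "edge_mask_result")) {
    te <- x$top_edges
    utils::head(paste(te$region_i, te$region_j, sep = " | "), top_k)
  } else {
    abort_bad_arg("rank_consensus needs ablation_result or edge_mask_result.")
  }
}

#' Consensus of two attribution rankings
#'
#' Intersects the top-k sets of two attribution results computed on
#' different cohorts (regions for ablation, edges for the explainer) and
#' orders the shared items by mean rank. Items found by both cohorts are the
#' replicated findings.
#'
#' @param result_a,result_b Two `ablation_result`s or two
#'   `edge_mask_result`s over the same region labels.
#' @param top_k Depth of the rankings compared (default 10).
#' @return Tibble with `id`, `rank_a`, `rank_b`, `mean_rank`, ordered by
#'   mean rank (ties by id).
#' @export
rank_consensus <- function(result_a, result_b, top_k = 10L) {
  if (!identical(result_a$region_labels, result_b$region_labels)) {
    abort_bad_arg("region labels differ between results.")
  }
  ids_a <- ranked_ids(result_a, top_k)
  ids_b <- ranked_ids(result_b, top_k)
  shared <- intersect(ids_a, ids_b)
  out <- tibble::tibble(
    id = shared,
    rank_a = match(shared, ids_a),
    rank_b = match(shared, ids_b))
  out$mean_rank <- (out$rank_a + out$rank_b) / 2
  dplyr::arrange(out, .data$mean_rank, .data$id)
}
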