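# Graph convolutional network, written against base matrix algebra with a
# sparse block-diagonal batch layout (Matrix). Layer rule H <- relu(Ahat H W)
# over the symmetric renormalized propagation matrix, mean pooling over
# nodes, a dense output layer, sigmoid + binary cross entropy for
# classification (identity + mean squared error for regression). Optimized
# with minibatch Adam under a step schedule: initial learning rate decayed
# by a fixed factor on a fixed epoch interval.

# Stack a list of graphs into batch structures: dense node-feature stack
# (nR x R), sparse block-diagonal propagation matrix (nR x nR) and a sparse
# mean-pooling matrix (n x nR).
gcn_batch <- function(graphs) {
  n <- length(graphs)
  r <- nrow(graphs[[1]]$adjacency)
  x_big <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  trip <- vector("list", n)
  for (s in seq_len(n)) {
    ahat <- normalize_adjacency(graphs[[s]]$adjacency)
    nz <- which(ahat != 0, arr.ind = TRUE)
    off <- (s - 1L) * r
    trip[[s]] <- cbind(nz[, 1] + off, nz[, 2] + off, ahat[nz])
  }
  trip <- do.call(rbind, trip)
  a_big <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                                dims = c(n * r, n * r))
  pool <- Matrix::sparseMatrix(i = rep(seq_len(n), each = r),
                               j = seq_len(n * r), x = 1 / r,
                               dims = c(n, n * r))
  list(n = n, r = r, x = x_big, a = a_big, pool = pool)
}

gcn_init_params <- function(r, hidden, n_layers, seed) {
  set.seed(seed)
  w <- vector("list", n_layers)
  bl <- vector("list", n_layers)
  if (n_layers >= 1) {
    w[[1]] <- matrix(rnorm(r * hidden, 0, sqrt(2 / r)), r, hidden)
    for (l in seq_len(n_layers - 1L) + 1L) {
      w[[l]] <- matrix(rnorm(hidden * hidden, 0, sqrt(2 / hidden)), hidden, hidden)
    }
    # small positive bias keeps ReLU units alive early in training
    for (l in seq_len(n_layers)) bl[[l]] <- rep(0.1, hidden)
  }
  out_dim <- if (n_layers >= 1) hidden else r
  list(w = w, bl = bl,
       w_out = matrix(rnorm(out_dim, 0, sqrt(1 / out_dim)), out_dim, 1),
       b = 0)
}

# Forward pass over a batch. Returns activations needed for backprop.
gcn_forward <- function(params, batch, dropout = 0, train = FALSE) {
  h <- batch$x
  n_layers <- length(params$w)
  inputs <- vector("list", n_layers)
  pres <- vector("list", n_layers)
  masks <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    inputs[[l]] <- h
    pre <- as.matrix(batch$a %*% (h %*% params$w[[l]]))
    bias_l <- params$bl[[l]] %||% numeric(ncol(pre))
    pre <- sweep(pre, 2, bias_l, `+`)
    pres[[l]] <- pre
    h <- pmax(pre, 0)
    if (train && dropout > 0) {
      m <- matrix((runif(length(h)) >= dropout) / (1 - dropout),
                  nrow(h), ncol(h))
      masks[[l]] <- m
      h <- h * m
    }
  }
  pooled <- as.matrix(batch$pool %*% h)
  score <- drop(pooled %*% params$w_out) + params$b
  list(score = score, pooled = pooled, inputs = inputs, pres = pres,
       masks = masks)
}

#' Train a graph convolutional classifier or regressor
#'
#' Stacked graph convolutions `H <- relu(Ahat H W)` over the renormalized
#' propagation matrix of each subject's graph, mean-pooled over nodes,
#' followed by a dense layer; sigmoid output trained with binary cross
#' entropy (classification) or linear output with mean squared error
#' (regression). Full-batch Adam with a step learning-rate decay schedule
#' and inverted dropout on hidden activations; seeded weight initialization.
#'
#' @param graphs List of `connectome_graph` objects.
#' @param y Factor (two levels; second level = positive class) or 0/1 vector
#'   for classification; numeric vector for regression.
#' @param hidden Hidden width of the convolution layers.
#' @param n_layers Number of convolution layers (0 reduces the model to a
#'   dense net on mean node features).
#' @param epochs,lr,decay_every,decay_factor Training schedule (defaults:
#'   100 epochs, initial learning rate 0.001 decaying by a factor of 10
#'   every 30 epochs).
#' @param dropout Dropout rate on hidden activations during training.
#' @param batch_size Minibatch size (subjects per Adam step; default 32).
#' @param regression Fit a regressor instead of a classifier?
#' @param restarts For classifiers: number of re-initializations attempted
#'   when a run collapses to constant output (all hidden units dead, a known
#'   failure mode of ReLU networks); default 2. Each restart derives a new
#'   seed deterministically from `seed`.
#' @param seed Seed for initialization and dropout.
#' @return A `gcn_model` with weights, the training loss trace, and (for
#'   classification) the class `levels`.
#' @export
gcn_train <- function(graphs, y, hidden = 64L, n_layers = 2L,
                      epochs = 100L, lr = 1e-3, decay_every = 30L,
                      decay_factor = 10, dropout = 0.5, batch_size = 32L,
                      regression = FALSE, restarts = 2L, seed = 1L) {
  for (attempt in 0:restarts) {
    model <- gcn_train_once(graphs, y, hidden = hidden, n_layers = n_layers,
                            epochs = epochs, lr = lr,
                            decay_every = decay_every,
                            decay_factor = decay_factor, dropout = dropout,
                            batch_size = batch_size, regression = regression,
                            seed = seed + 104729L * attempt)
    if (regression) return(model)
    p_tr <- gcn_predict(model, graphs)
    if (diff(range(p_tr)) > 0.05) return(model)
  }
  model
}

gcn_train_once <- function(graphs, y, hidden = 64L, n_layers = 2L,
                           epochs = 100L, lr = 1e-3, decay_every = 30L,
                           decay_factor = 10, dropout = 0.5, batch_size = 32L,
                           regression = FALSE, seed = 1L) {
  stopifnot(length(graphs) == length(y), length(graphs) >= 2)
  levels_y <- NULL
  if (!regression) {
    if (is.factor(y)) {
      y <- droplevels(y)
      levels_y <- levels(y)
      y <- as.numeric(y) - 1
    } else {
      levels_y <- c("0", "1")
      y <- as.numeric(y)
    }
    stopifnot(all(y %in% c(0, 1)))
  }
  n_all <- length(graphs)
  set.seed(seed)
  # fixed shuffled minibatch partition; batch structures assembled once
  perm <- sample(n_all)
  n_batches <- max(1L, ceiling(n_all / batch_size))
  batch_idx <- split(perm, rep(seq_len(n_batches), length.out = n_all,
                               each = ceiling(n_all / n_batches)))
  batches <- lapply(batch_idx, function(ix) {
    list(data = gcn_batch(graphs[ix]), y = y[ix])
  })
  r <- nrow(graphs[[1]]$adjacency)
  params <- gcn_init_params(r, hidden, n_layers, seed)
  adam <- list(m = rapply(params, function(p) p * 0, how = "replace"),
               v = rapply(params, function(p) p * 0, how = "replace"),
               t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  losses <- numeric(epochs)

  for (epoch in seq_len(epochs)) {
    lr_t <- lr / decay_factor^(floor((epoch - 1) / decay_every))
    epoch_loss <- 0
    for (bi in sample(n_batches)) {
      batch <- batches[[bi]]$data
      yb <- batches[[bi]]$y
      n <- batch$n
      fw <- gcn_forward(params, batch, dropout = dropout, train = TRUE)
      if (regression) {
        pred <- fw$score
        loss <- mean((pred - yb)^2)
        dscore <- 2 * (pred - yb) / n
      } else {
        p <- stats::plogis(fw$score)
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        dscore <- (p - yb) / n
      }
      if (!is.finite(loss)) {
        stop(sprintf("non-finite GCN loss at epoch %d.", epoch), call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss * n / n_all

      grads <- list(w = vector("list", n_layers),
                    bl = vector("list", n_layers), w_out = NULL, b = NULL)
      grads$w_out <- crossprod(fw$pooled, dscore)
      grads$b <- sum(dscore)
      dh <- as.matrix(Matrix::crossprod(batch$pool,
                                        cbind(dscore) %*% t(params$w_out)))
      for (l in rev(seq_len(n_layers))) {
        if (!is.null(fw$masks[[l]])) dh <- dh * fw$masks[[l]]
        dpre <- dh * (fw$pres[[l]] > 0)
        grads$bl[[l]] <- colSums(dpre)
        dz <- as.matrix(batch$a %*% dpre)  # propagation matrix is symmetric
        grads$w[[l]] <- crossprod(fw$inputs[[l]], dz)
        if (l > 1L) dh <- dz %*% t(params$w[[l]])
      }

      adam$t <- adam$t + 1
      upd <- function(p, g, slot) {
        adam$m[[slot]] <<- beta1 * adam$m[[slot]] + (1 - beta1) * g
        adam$v[[slot]] <<- beta2 * adam$v[[slot]] + (1 - beta2) * g^2
        mhat <- adam$m[[slot]] / (1 - beta1^adam$t)
        vhat <- adam$v[[slot]] / (1 - beta2^adam$t)
        p - lr_t * mhat / (sqrt(vhat) + eps)
      }
      for (l in seq_len(n_layers)) {
        adam$m$w[[l]] <- beta1 * adam$m$w[[l]] + (1 - beta1) * grads$w[[l]]
        adam$v$w[[l]] <- beta2 * adam$v$w[[l]] + (1 - beta2) * grads$w[[l]]^2
        mhat <- adam$m$w[[l]] / (1 - beta1^adam$t)
        vhat <- adam$v$w[[l]] / (1 - beta2^adam$t)
        params$w[[l]] <- params$w[[l]] - lr_t * mhat / (sqrt(vhat) + eps)
        adam$m$bl[[l]] <- beta1 * adam$m$bl[[l]] + (1 - beta1) * grads$bl[[l]]
        adam$v$bl[[l]] <- beta2 * adam$v$bl[[l]] + (1 - beta2) * grads$bl[[l]]^2
        mhat_b <- adam$m$bl[[l]] / (1 - beta1^adam$t)
        vhat_b <- adam$v$bl[[l]] / (1 - beta2^adam$t)
        params$bl[[l]] <- params$bl[[l]] - lr_t * mhat_b / (sqrt(vhat_b) + eps)
      }
      params$w_out <- upd(params$w_out, grads$w_out, "w_out")
      params$b <- upd(params$b, grads$b, "b")
    }
    losses[epoch] <- epoch_loss
  }

  structure(list(w = params$w, bl = params$bl, w_out = params$w_out,
                 b = params$b,
                 hidden = hidden, n_layers = n_layers,
                 regression = regression, levels = levels_y,
                 losses = losses,
                 region_labels = graphs[[1]]$region_labels),
            class = "gcn_model")
}

#' Predict with a trained GCN
#'
#' @param model A `gcn_model` (from [gcn_train()] or [new_gcn_model()]).
#' @param graphs List of `connectome_graph` objects.
#' @return Predicted class-1 probabilities (classification) or values
#'   (regression).
#' @export
gcn_predict <- function(model, graphs) {
  batch <- gcn_batch(graphs)
  fw <- gcn_forward(model, batch, dropout = 0, train = FALSE)
  if (model$regression) fw$score else stats::plogis(fw$score)
}

#' Construct a GCN model from explicit weights
#'
#' Builds a `gcn_model` directly from weight matrices, e.g. to hand-craft a
#' classifier whose output depends on a known part of the graph.
#'
#' @param w List of convolution weight matrices (may be empty).
#' @param w_out Output-layer weight vector/matrix.
#' @param b Output bias.
#' @param regression Is the output linear rather than sigmoid?
#' @param levels Class labels for classification.
#' @param region_labels Optional region labels.
#' @return A `gcn_model`.
#' @export
new_gcn_model <- function(w, w_out, b = 0, bl = NULL, regression = FALSE,
                          levels = c("neg", "pos"), region_labels = NULL) {
  w_out <- as.matrix(w_out)
  bl <- bl %||% lapply(w, function(wl) numeric(ncol(wl)))
  structure(list(w = w, bl = bl, w_out = w_out, b = b,
                 hidden = if (length(w)) ncol(w[[length(w)]]) else nrow(w_out),
                 n_layers = length(w), regression = regression,
                 levels = levels, losses = numeric(0),
                 region_labels = region_labels),
            class = "gcn_model")
}
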