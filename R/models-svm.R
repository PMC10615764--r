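# SVM / SVR engine. Fits go through kernlab (C-svc / eps-svr) on precomputed
# kernel matrices: the Gram matrix over the whole experiment's subjects is
# computed once and sliced per fold, which makes permutation refits (features
# fixed, labels shuffled) cheap.

#' Model specification
#'
#' Describes a model family, its hyperparameter grid and training budget.
#' Families: `svm_linear` and `svm_rbf` (support vector classification on
#' upper-triangle FC features), `gcn` (graph convolutional classifier on
#' connectome graphs), `svr_rbf` and `gcn_regressor` (severity regression).
#'
#' Default grids: C in \{0.01, 0.1, 1, 10, 100\} for linear SVM; the same C
#' crossed with a kernel width multiplier gamma_mult in \{0.1, 1, 10\} of the
#' scale heuristic `1 / (P * var(X))` for rbf models; hidden width
#' \{64, 128\} crossed with \{2, 3\} convolution layers for the GCN.
#'
#' @param family One of `"svm_linear"`, `"svm_rbf"`, `"gcn"`, `"svr_rbf"`,
#'   `"gcn_regressor"`.
#' @param grid Data frame of hyperparameter combinations (one row each);
#'   `NULL` for the family default.
#' @param sparsity Graph sparsity for GCN models (fraction of edges kept).
#' @param epochs,lr,decay_every,decay_factor GCN training schedule: Adam with
#'   initial learning rate `lr` decaying by `decay_factor` every `decay_every`
#'   epochs, for `epochs` epochs (defaults 0.001, 10, 30, 100).
#' @param dropout GCN dropout rate on hidden node activations.
#' @param batch_size GCN minibatch size (default 32).
#' @param hidden,n_layers GCN architecture used when the grid does not vary
#'   them.
#' @return A `model_spec` object.
#' @examples
#' model_spec("svm_rbf", grid = data.frame(C = 1, gamma_mult = 1))
#' @export
model_spec <- function(family = c("svm_linear", "svm_rbf", "gcn",
                                  "svr_rbf", "gcn_regressor"),
                       grid = NULL, sparsity = 0.5,
                       epochs = 100L, lr = 1e-3,
                       decay_every = 30L, decay_factor = 10,
                       dropout = 0.5, hidden = 64L, n_layers = 2L,
                       batch_size = 32L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      svm_linear = tibble::tibble(C = c(0.01, 0.1, 1, 10, 100)),
      svm_rbf = ,
      svr_rbf = tidyr::crossing(C = c(0.01, 0.1, 1, 10, 100),
                                gamma_mult = c(0.1, 1, 10)),
      gcn = ,
      gcn_regressor = tidyr::crossing(hidden = c(64L, 128L), n_layers = 2:3))
  }
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) abort_bad_arg("hyperparameter grid must be nonempty.")
  structure(list(family = family, grid = grid, sparsity = sparsity,
                 epochs = as.integer(epochs), lr = lr,
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor, dropout = dropout,
                 hidden = as.integer(hidden), n_layers = as.integer(n_layers),
                 batch_size = as.integer(batch_size)),
            class = "model_spec")
}

is_gcn_family <- function(family) family %in% c("gcn", "gcn_regressor")
is_regression_family <- function(family) family %in% c("svr_rbf", "gcn_regressor")

# sklearn-style "scale" heuristic for the rbf width: 1 / (P * Var(X)).
rbf_gamma_scale <- function(x) {
  v <- mean(x^2) - mean(x)^2
  if (v <= 0) v <- 1
  1 / (ncol(x) * v)
}

cross_kernel <- function(x_new, x_ref, family, gamma = NULL) {
  g <- x_new %*% t(x_ref)
  if (family == "svm_linear") return(g)
  d2 <- outer(rowSums(x_new^2), rowSums(x_ref^2), "+") - 2 * g
  exp(-gamma * pmax(d2, 0))
}

# Engine interface: fit(idx, y, hyper, seed) / predict(model, idx). The SVM
# engine caches one full kernel matrix per gamma value.
build_svm_engine <- function(spec, x) {
  force(x)
  gram <- NULL
  sq <- rowSums(x^2)
  gamma_scale <- rbf_gamma_scale(x)
  kernels <- new.env(parent = emptyenv())

  get_gram <- function() {
    if (is.null(gram)) gram <<- tcrossprod(x)
    gram
  }
  get_kernel <- function(hyper) {
    if (spec$family == "svm_linear") return(get_gram())
    gamma <- (hyper$gamma_mult %||% 1) * gamma_scale
    key <- sprintf("%.12g", gamma)
    if (is.null(kernels[[key]])) {
      d2 <- outer(sq, sq, "+") - 2 * get_gram()
      kernels[[key]] <- exp(-gamma * pmax(d2, 0))
    }
    kernels[[key]]
  }

  regression <- is_regression_family(spec$family)
  fit <- function(idx, y, hyper, seed = 1L) {
    k <- get_kernel(hyper)
    if (!regression) {
      y <- droplevels(factor(y))
      if (nlevels(y) < 2) {
        return(list(constant = levels(y)[1], idx = idx, hyper = hyper))
      }
    }
    m <- kernlab::ksvm(kernlab::as.kernelMatrix(k[idx, idx, drop = FALSE]),
                       y, type = if (regression) "eps-svr" else "C-svc",
                       C = hyper$C %||% 1)
    list(model = m, idx = idx, hyper = hyper)
  }
  predict_fn <- function(model, idx_new) {
    if (!is.null(model$constant)) {
      return(factor(rep(model$constant, length(idx_new))))
    }
    k <- get_kernel(model$hyper)
    kt <- k[idx_new, model$idx, drop = FALSE]
    kt <- kt[, kernlab::SVindex(model$model), drop = FALSE]
    kernlab::predict(model$model, kernlab::as.kernelMatrix(kt))
  }
  list(family = spec$family, spec = spec, n = nrow(x),
       fit = fit, predict = predict_fn, x = x,
       gamma_scale = gamma_scale)
}

build_gcn_engine <- function(spec, graphs) {
  force(graphs)
  regression <- is_regression_family(spec$family)
  fit <- function(idx, y, hyper, seed = 1L) {
    m <- gcn_train(graphs[idx],
                   y = if (regression) as.numeric(y) else y,
                   hidden = hyper$hidden %||% spec$hidden,
                   n_layers = hyper$n_layers %||% spec$n_layers,
                   epochs = spec$epochs, lr = spec$lr,
                   decay_every = spec$decay_every,
                   decay_factor = spec$decay_factor,
                   dropout = spec$dropout, batch_size = spec$batch_size,
                   regression = regression, seed = seed)
    list(model = m, idx = idx, hyper = hyper)
  }
  predict_fn <- function(model, idx_new) {
    out <- gcn_predict(model$model, graphs[idx_new])
    if (regression) return(out)
    lev <- model$model$levels
    factor(lev[(out >= 0.5) + 1L], levels = lev)
  }
  list(family = spec$family, spec = spec, n = length(graphs),
       fit = fit, predict = predict_fn, graphs = graphs)
}

# Build the right engine for a model family from a cohort.
build_engine <- function(spec, cohort) {
  if (is_gcn_family(spec$family)) {
    build_gcn_engine(spec, cohort_graphs(cohort, sparsity = spec$sparsity))
  } else {
    build_svm_engine(spec, fc_features(cohort))
  }
}

#' Fit a single model on a full dataset
#'
#' Fits one model (no cross-validation) and returns an object exposing
#' `predict_probability()` / `predict_value()` via [predict()]. SVM families
#' take an n x P feature matrix (see [fc_features()]); GCN families take a
#' list of `connectome_graph` objects.
#'
#' @param x Feature matrix or list of graphs.
#' @param y Labels: factor (classification, second level = positive class) or
#'   numeric (regression).
#' @param spec A [model_spec()].
#' @param hyper One-row data frame of hyperparameters; default = first grid row.
#' @param seed Seed for stochastic fits.
#' @return A `conn_model` object.
#' @export
fit_model <- function(x, y, spec, hyper = NULL, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  hyper <- hyper %||% spec$grid[1, , drop = FALSE]
  engine <- if (is_gcn_family(spec$family)) build_gcn_engine(spec, x)
            else build_svm_engine(spec, x)
  fitted <- engine$fit(seq_len(engine$n), y, hyper, seed = seed)
  structure(list(engine = engine, fitted = fitted, spec = spec,
                 hyper = hyper), class = "conn_model")
}

#' @export
predict.conn_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$engine$predict(object$fitted, seq_len(object$engine$n)))
  }
  if (is_gcn_family(object$spec$family)) {
    out <- gcn_predict(object$fitted$model, newdata)
    if (is_regression_family(object$spec$family)) return(out)
    lev <- object$fitted$model$levels
    return(factor(lev[(out >= 0.5) + 1L], levels = lev))
  }
  gamma <- if (object$spec$family == "svm_linear") NULL else
    (object$hyper$gamma_mult %||% 1) * object$engine$gamma_scale
  kt <- cross_kernel(newdata, object$engine$x, object$spec$family, gamma)
  if (!is.null(object$fitted$constant)) {
    return(factor(rep(object$fitted$constant, nrow(newdata))))
  }
  kt <- kt[, kernlab::SVindex(object$fitted$model), drop = FALSE]
  kernlab::predict(object$fitted$model, kernlab::as.kernelMatrix(kt))
}
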