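# Supervised discrimination of SCI vs healthy cycles: a small fully connected
# network (one ReLU hidden layer, dropout, Adam, logistic output) trained on
# the flattened 4 x 101 angle features.

#' MLP training configuration
#'
#' One hidden layer of \code{hidden_width} rectified units, inverted-dropout
#' regularization, the Adam optimizer on full-batch binary cross-entropy, and
#' a logistic output for the probability of the positive (SCI) class. The
#' published description of the architecture is ambiguous about depth;
#' a single hidden layer of width 100 (the common hidden-size reading) is the
#' default and both are configurable.
#'
#' @param hidden_width Hidden units (default 100).
#' @param max_iterations Adam iterations (default 300).
#' @param dropout_rate Hidden-unit dropout probability in \code{[0, 1)}
#'   (default 0.2).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed controlling initialization, dropout masks and the
#'   held-out split.
#' @return An object of class \code{mlp_config}.
#' @export
mlp_config <- function(hidden_width = 100L, max_iterations = 300L,
                       dropout_rate = 0.2, learning_rate = 1e-3, seed = 1L) {
  check_number(hidden_width, "hidden_width", lower = 1)
  check_number(max_iterations, "max_iterations", lower = 1)
  check_number(dropout_rate, "dropout_rate", lower = 0, upper = 1,
               closed_upper = FALSE)
  check_number(learning_rate, "learning_rate", lower = 0, closed_lower = FALSE)
  structure(list(hidden_width = as.integer(hidden_width),
                 max_iterations = as.integer(max_iterations),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

cycles_feature_matrix <- function(cycles) {
  if (is.matrix(cycles) && ncol(cycles) == 404L) return(cycles)
  cycles_to_matrix(cycles)
}

#' Train the MLP gait classifier
#'
#' Features are the flattened 4 x 101 cycle matrices, standardized with the
#' training-set mean and standard deviation. A stratified fraction of each
#' class is held out before training and used to report honest
#' classification metrics. Training is fully deterministic given
#' \code{config$seed}.
#'
#' @param cycles List of \code{\link{normalized_cycle}} objects or an
#'   n x 404 feature matrix.
#' @param labels Class label per cycle; exactly 2 classes.
#' @param config An \code{\link{mlp_config}}.
#' @param holdout_fraction Fraction of each class held out for evaluation
#'   (default 0.25; 0 disables the split and metrics are resubstitution).
#' @param positive_label Positive class for the output probability and the
#'   metrics (default \code{"SCI"}, falling back to the last sorted label).
#' @return An object of class \code{mlp_classifier} with the learned weights,
#'   feature scaling, \code{metrics} (a \code{\link{compute_metrics}} result
#'   on the held-out set) and the row indices of the held-out cycles.
#' @export
train_classifier <- function(cycles, labels, config = mlp_config(),
                             holdout_fraction = 0.25,
                             positive_label = NULL) {
  stopifnot(inherits(config, "mlp_config"))
  X <- cycles_feature_matrix(cycles)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stopf("`cycles` and `labels` length mismatch")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stopf("exactly 2 classes are required, got %d",
                                   length(classes))
  if (is.null(positive_label)) {
    positive_label <- if ("SCI" %in% classes) "SCI" else classes[2L]
  }
  y <- as.numeric(labels == positive_label)
  with_seed(config$seed, {
    test_idx <- integer()
    if (holdout_fraction > 0) {
      for (cl in classes) {
        members <- which(labels == cl)
        n_test <- max(1L, floor(holdout_fraction * length(members)))
        test_idx <- c(test_idx, sample(members, n_test))
      }
      test_idx <- sort(test_idx)
    }
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    center <- colMeans(X[train_idx, , drop = FALSE])
    scl <- apply(X[train_idx, , drop = FALSE], 2L, sd)
    scl[scl < 1e-8] <- 1
    Z <- sweep(sweep(X[train_idx, , drop = FALSE], 2L, center), 2L, scl, `/`)
    fit <- mlp_fit(Z, y[train_idx], config)
    model <- structure(
      c(fit, list(center = center, scale = scl, classes = classes,
                  positive_label = positive_label, config = config,
                  holdout_idx = test_idx)),
      class = "mlp_classifier")
    eval_idx <- if (length(test_idx) > 0L) test_idx else train_idx
    pred <- predict(model, X[eval_idx, , drop = FALSE], type = "label")
    model$metrics <- compute_metrics(labels[eval_idx], pred,
                                     positive_label = positive_label)
    model
  })
}

# Adam on full-batch binary cross-entropy; He-initialized single hidden layer.
mlp_fit <- function(Z, y, config) {
  n <- nrow(Z); p <- ncol(Z); h <- config$hidden_width
  W1 <- matrix(rnorm(p * h, 0, sqrt(2 / p)), p, h)
  b1 <- numeric(h)
  W2 <- matrix(rnorm(h, 0, sqrt(2 / h)), h, 1L)
  b2 <- 0
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(x) x * 0)
  vel <- lapply(params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  keep <- 1 - config$dropout_rate
  for (it in seq_len(config$max_iterations)) {
    H_lin <- sweep(Z %*% params$W1, 2L, params$b1, `+`)
    H <- pmax(H_lin, 0)
    if (config$dropout_rate > 0) {
      mask <- matrix(runif(n * h) < keep, n, h) / keep
      H <- H * mask
    }
    o <- as.numeric(H %*% params$W2) + params$b2
    prob <- 1 / (1 + exp(-o))
    delta_o <- (prob - y) / n                    # d(BCE)/d(o)
    grad <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(H, delta_o), b2 = sum(delta_o))
    dH <- tcrossprod(delta_o, as.numeric(params$W2))
    if (config$dropout_rate > 0) dH <- dH * mask
    dH <- dH * (H_lin > 0)
    grad$W1 <- crossprod(Z, dH)
    grad$b1 <- colSums(dH)
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grad[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grad[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^it)
      vhat <- vel[[nm]] / (1 - beta2^it)
      params[[nm]] <- params[[nm]] - config$learning_rate *
        mhat / (sqrt(vhat) + eps)
    }
  }
  params
}

#' Predict SCI probability or labels from a trained MLP
#'
#' @param object An \code{\link{mlp_classifier}}.
#' @param newdata Cycles (list), a single cycle, or an n x 404 raw feature
#'   matrix.
#' @param type \code{"prob"} (probability of the positive class) or
#'   \code{"label"}.
#' @param ... Unused.
#' @return Numeric probabilities or character labels.
#' @export
predict.mlp_classifier <- function(object, newdata, type = c("prob", "label"),
                                   ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata) && ncol(newdata) == 404L) newdata else {
    if (inherits(newdata, "normalized_cycle")) newdata <- list(newdata)
    cycles_feature_matrix(newdata)
  }
  Z <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  H <- pmax(sweep(Z %*% object$W1, 2L, object$b1, `+`), 0)
  o <- as.numeric(H %*% object$W2) + object$b2
  prob <- 1 / (1 + exp(-o))
  if (type == "prob") return(prob)
  neg <- setdiff(object$classes, object$positive_label)
  ifelse(prob >= 0.5, object$positive_label, neg)
}

#' @export
print.mlp_classifier <- function(x, ...) {
  cat(sprintf("<mlp_classifier> 404-%d-1 (ReLU, dropout %.2f), %d Adam iterations\n",
              x$config$hidden_width, x$config$dropout_rate,
              x$config$max_iterations))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
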