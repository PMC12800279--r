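# Shapley-value attribution of per-timepoint angle features and extraction of
# significant (discriminative) gait-cycle time windows.

#' Monte-Carlo Shapley attribution of a cycle classification
#'
#' Permutation-sampling approximation of Shapley values over the 404
#' (channel, timepoint) features: for each of \code{n_samples} draws, a
#' random feature ordering and a random background cycle are sampled, the
#' features of the explained instance are switched in one at a time in that
#' order, and the change in model output at each switch is credited to the
#' switched feature. Missing features are imputed from the drawn background
#' cycle. By construction the estimate is exactly additive:
#' \code{baseline + sum(values)} equals the model output for the instance up
#' to floating point, where \code{baseline} is the mean model output over the
#' drawn backgrounds.
#'
#' @param model An \code{\link{mlp_classifier}} (its positive-class
#'   probability is explained) or any function mapping an n x 404 feature
#'   matrix to n numeric outputs.
#' @param background List of cycles (or matrix) the imputation draws from —
#'   typically the training set.
#' @param instance The cycle (or length-404 vector) to explain.
#' @param n_samples Number of sampled feature orderings (default 512).
#' @param seed Optional integer seed.
#' @return An object of class \code{attribution_map}: \code{values} (101 x 4
#'   signed matrix, model-output units), \code{baseline},
#'   \code{prediction} (model output at the instance), \code{n_samples},
#'   \code{seed}.
#' @export
shap_attribution <- function(model, background, instance, n_samples = 512L,
                             seed = NULL) {
  if (n_samples < 1L) stopf("`n_samples` must be at least 1")
  f <- if (is.function(model)) model else {
    if (!inherits(model, "mlp_classifier")) {
      stopf("`model` must be an mlp_classifier or a function")
    }
    function(X) predict(model, X, type = "prob")
  }
  B <- cycles_feature_matrix(background)
  if (nrow(B) < 1L) stopf("`background` must be non-empty")
  x <- if (is.numeric(instance) && length(instance) == 404L) {
    as.numeric(instance)
  } else flatten_cycle(instance)
  p <- 404L
  run <- function() {
    phi <- numeric(p)
    baseline_sum <- 0
    for (k in seq_len(n_samples)) {
      perm <- sample.int(p)
      bg <- B[sample.int(nrow(B), 1L), ]
      M <- matrix(bg, nrow = p + 1L, ncol = p, byrow = TRUE)
      vals <- x[perm]
      for (j in seq_len(p)) M[(j + 1L):(p + 1L), perm[j]] <- vals[j]
      out <- f(M)
      baseline_sum <- baseline_sum + out[1L]
      phi[perm] <- phi[perm] + diff(out)
    }
    list(phi = phi / n_samples, baseline = baseline_sum / n_samples)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(values = unflatten_cycle(res$phi), baseline = res$baseline,
                 prediction = f(matrix(x, nrow = 1L))[1L],
                 n_samples = as.integer(n_samples), seed = seed),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf(
    "<attribution_map> baseline=%.4f, prediction=%.4f, additivity gap=%.2e (n=%d)\n",
    x$baseline, x$prediction, abs(x$baseline + sum(x$values) - x$prediction),
    x$n_samples))
  invisible(x)
}

#' Extract significant time windows from an attribution map
#'
#' Per channel, cycle positions whose absolute attribution exceeds a
#' threshold (default: mean + 2 standard deviations of the absolute
#' attributions across all 404 features — an explicit, overridable rule for
#' drawing bounding boxes on attribution plots) are merged into contiguous
#' windows. Each window's sign states whether raising the angle in
#' that window increases or decreases the predicted SCI probability; windows
#' are ranked by their total absolute attribution mass.
#'
#' @param map An \code{\link{attribution_map}}.
#' @param threshold Absolute-attribution cutoff; \code{NULL} (default) uses
#'   the mean + 2 SD rule.
#' @return Data frame ordered by decreasing mass with columns \code{channel,
#'   start, end} (cycle percent, inclusive), \code{sign, mean_attribution,
#'   mass}.
#' @export
extract_windows <- function(map, threshold = NULL) {
  stopifnot(inherits(map, "attribution_map"))
  v <- map$values
  if (any(!is.finite(v))) stopf("attribution map must be finite")
  av <- abs(as.vector(v))
  if (is.null(threshold)) threshold <- mean(av) + 2 * sd(av)
  rows <- list()
  for (ch in gait_channels()) {
    above <- abs(v[, ch]) > threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      seg <- v[starts[r]:ends[r], ch]
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, start = starts[r] - 1L, end = ends[r] - 1L,
        sign = if (mean(seg) > 0) "increases-SCI-probability"
               else "decreases-SCI-probability",
        mean_attribution = mean(seg), mass = sum(abs(seg)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(channel = character(), start = integer(),
                      end = integer(), sign = character(),
                      mean_attribution = numeric(), mass = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$mass), , drop = FALSE]
}
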