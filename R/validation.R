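# Validation statistics: dynamic time warping, DTW permutation test and
# Pearson correlation of angle signatures against a reference.

as_time_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (nrow(m) == 0L) stopf("sequences must be non-empty")
  if (any(!is.finite(m))) stopf("sequences must be finite")
  m
}

#' Dynamic time warping distance and optimal path
#'
#' Classic unconstrained dynamic-programming recurrence with steps
#' \code{(i-1,j-1), (i-1,j), (i,j-1)}; the pointwise distance is the absolute
#' difference for univariate sequences and the Euclidean norm for multivariate
#' ones (rows = time points). The distance is the unnormalized sum of
#' pointwise distances along the optimal warping path; an optional
#' normalization by path length is provided but off by default.
#'
#' @param x,y Numeric vectors or time x channel matrices.
#' @param normalize Divide the distance by the path length (default
#'   \code{FALSE}).
#' @return List of class \code{dtw_result}: \code{distance} and \code{path}
#'   (two-column matrix of 1-based index pairs from \code{(1,1)} to
#'   \code{(n,m)}).
#' @export
dtw_distance <- function(x, y, normalize = FALSE) {
  X <- as_time_matrix(x); Y <- as_time_matrix(y)
  if (ncol(X) != ncol(Y)) stopf("x and y must share their channels")
  res <- dtw_path_cpp(X, Y)
  d <- res$distance
  if (normalize) d <- d / nrow(res$path)
  structure(list(distance = d, path = res$path, normalized = normalize),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance=%.4g over a path of length %d\n",
              x$distance, nrow(x$path)))
  invisible(x)
}

#' Permutation test for DTW similarity of two time series
#'
#' Compares the observed DTW distance to a null distribution obtained by
#' randomly permuting the time order of the comparator series \code{y}
#' (jointly across channels) \code{n_permutations} times, recomputing the
#' distance each time. The p-value is the fraction of null distances at or
#' below the observed one, \eqn{p = N^{-1}\sum_k \mathbb{I}(D^{(k)} \le
#' D_{obs})}; small p means the two series are more similar than chance
#' re-orderings. The literal estimator can return 0; \code{plus_one} switches
#' to the \eqn{(1+\sum \mathbb{I})/(1+N)} smoothed version.
#'
#' @param x,y Numeric vectors or time x channel matrices (length >= 3).
#' @param n_permutations Number of permutations (default 8000).
#' @param seed Optional integer seed; \code{NULL} uses the current RNG stream.
#' @param plus_one Use add-one smoothing (default \code{FALSE}).
#' @return List of class \code{permutation_test_result}: \code{observed},
#'   \code{null_distances}, \code{p_value}, \code{n_permutations},
#'   \code{seed}.
#' @export
dtw_permutation_test <- function(x, y, n_permutations = 8000L, seed = NULL,
                                 plus_one = FALSE) {
  X <- as_time_matrix(x); Y <- as_time_matrix(y)
  if (nrow(X) < 3L || nrow(Y) < 3L) stopf("sequences must have length >= 3")
  if (n_permutations < 1L) stopf("`n_permutations` must be at least 1")
  observed <- dtw_cost_cpp(X, Y)
  run <- function() {
    vapply(seq_len(n_permutations), function(k) {
      dtw_cost_cpp(X, Y[sample.int(nrow(Y)), , drop = FALSE])
    }, numeric(1))
  }
  null_d <- if (is.null(seed)) run() else with_seed(seed, run())
  hits <- sum(null_d <= observed)
  p <- if (plus_one) (1 + hits) / (1 + n_permutations) else hits / n_permutations
  structure(list(observed = observed, null_distances = null_d, p_value = p,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("<permutation_test_result> D_obs=%.4g, p=%.4g (N=%d)\n",
              x$observed, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' \eqn{r = \sum (x_i-\bar x)(y_i-\bar y) / \sqrt{\sum (x_i-\bar x)^2 \sum
#' (y_i-\bar y)^2}}, with the p-value from the t statistic
#' \eqn{r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom. Inputs with
#' zero variance are rejected rather than returned as 0.
#'
#' @param x,y Equal-length numeric vectors, \code{n >= 3}.
#' @return List of class \code{correlation_result}: \code{r}, \code{p_value},
#'   \code{n}.
#' @export
pearson_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stopf("at least 3 paired samples are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("inputs must be finite")
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx <= 0 || sy <= 0) stopf("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
  r <- min(max(r, -1), 1)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r=%.3f, p=%.3g (n=%d)\n",
              x$r, x$p_value, x$n))
  invisible(x)
}

#' Validate per-joint angle signatures against a reference
#'
#' Runs, per joint channel, univariate DTW (distance), the DTW permutation
#' test and Pearson correlation between a derived signature (e.g. a cluster
#' centroid or class mean on the 101-point grid) and a matched reference
#' signature (e.g. motion-capture derived).
#'
#' @param signatures,reference 101 x 4 matrices or
#'   \code{\link{normalized_cycle}} objects with matched channels.
#' @param n_permutations Permutations for the null distribution.
#' @param seed Integer seed for the permutation draws.
#' @param plus_one Passed to \code{\link{dtw_permutation_test}}.
#' @return Data frame with one row per joint: \code{joint, dtw_distance,
#'   p_permutation, r, p_correlation}.
#' @export
validate_signatures <- function(signatures, reference,
                                n_permutations = 8000L, seed = 1L,
                                plus_one = FALSE) {
  S <- cycle_matrix(signatures)
  R <- cycle_matrix(reference)
  rows <- lapply(seq_len(4L), function(j) {
    dtw <- dtw_cost_cpp(as_time_matrix(S[, j]), as_time_matrix(R[, j]))
    perm <- dtw_permutation_test(S[, j], R[, j],
                                 n_permutations = n_permutations,
                                 seed = seed + j, plus_one = plus_one)
    cr <- pearson_test(S[, j], R[, j])
    data.frame(joint = gait_channels()[j], dtw_distance = dtw,
               p_permutation = perm$p_value, r = cr$r,
               p_correlation = cr$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
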