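# Pose benchmarking: closed-form similarity (Procrustes) alignment and the
# Procrustes-aligned mean per-joint position error (PA-MPJPE).

as_landmark_matrix <- function(x) {
  if (inherits(x, "keypoint_trajectory")) {
    stopf("pass a single frame (landmark x 3 matrix); see pa_mpjpe_trajectory()")
  }
  m <- as.matrix(x)
  if (ncol(m) != 3L) stopf("expected a landmark x 3 coordinate matrix")
  m
}

#' Optimal similarity (Procrustes) alignment of predicted onto ground truth
#'
#' Finds the scale, proper rotation and translation minimizing the summed
#' squared distances between the transformed predicted landmarks and the
#' ground truth, in closed form: both sets are centred, the rotation comes
#' from the singular decomposition of the cross-covariance with the standard
#' reflection (sign-flip) correction so that anatomical left/right is never
#' mirrored away, and the positive scale is solved analytically as a ratio of
#' traces. Landmarks are matched by row name when both inputs are named,
#' otherwise by position.
#'
#' @param pred,gt Landmark x 3 coordinate matrices (mm) with at least 3
#'   non-collinear common landmarks.
#' @return List of class \code{procrustes_alignment} with \code{rotation}
#'   (3 x 3, det +1; applied to rows as \code{pred \%*\% rotation}),
#'   \code{scale}, \code{translation}, \code{aligned} (transformed predicted
#'   points) and \code{rss} (residual sum of squares).
#' @export
procrustes_align <- function(pred, gt) {
  P <- as_landmark_matrix(pred)
  G <- as_landmark_matrix(gt)
  if (!is.null(rownames(P)) && !is.null(rownames(G))) {
    common <- intersect(rownames(P), rownames(G))
    P <- P[common, , drop = FALSE]
    G <- G[common, , drop = FALSE]
  }
  if (nrow(P) != nrow(G)) stopf("pred and gt must share their landmarks")
  if (nrow(P) < 3L) stopf("at least 3 common landmarks are required")
  if (any(!is.finite(P)) || any(!is.finite(G))) {
    stopf("non-finite coordinates in alignment input")
  }
  cp <- colMeans(P); cg <- colMeans(G)
  Pc <- sweep(P, 2L, cp); Gc <- sweep(G, 2L, cg)
  ssP <- sum(Pc^2)
  M <- crossprod(Pc, Gc)                     # 3 x 3 cross-covariance
  sv <- svd(M)
  if (ssP < 1e-12 || sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stopf("rank-deficient landmark configuration: alignment is not unique")
  }
  sgn <- sign(det(sv$u %*% t(sv$v)))
  S <- diag(c(1, 1, sgn))
  rot <- sv$u %*% S %*% t(sv$v)              # rows: aligned = Pc %*% rot
  scale <- sum(diag(S) * sv$d) / ssP
  if (scale <= 0) stopf("non-positive optimal scale: degenerate input")
  aligned <- sweep(scale * Pc %*% rot, 2L, cg, `+`)
  rownames(aligned) <- rownames(P)
  structure(list(rotation = rot, scale = scale,
                 translation = as.numeric(cg - scale * cp %*% rot),
                 aligned = aligned, rss = sum((aligned - G)^2)),
            class = "procrustes_alignment")
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat(sprintf("<procrustes_alignment> scale=%.4f rss=%.4g mm^2\n",
              x$scale, x$rss))
  invisible(x)
}

#' Procrustes-aligned mean per-joint position error for one frame
#'
#' \deqn{PA\text{-}MPJPE = \frac{1}{N}\sum_{i=1}^{N} \lVert \hat{Y}_i - Y_i
#' \rVert_2,} where the predicted joint positions \eqn{\hat{Y}_i} have been
#' similarity-aligned onto the ground truth \eqn{Y_i} with
#' \code{\link{procrustes_align}}.
#'
#' @param pred,gt Landmark x 3 coordinate matrices (mm).
#' @return Mean per-joint error, mm.
#' @export
pa_mpjpe_frame <- function(pred, gt) {
  al <- procrustes_align(pred, gt)
  G <- as_landmark_matrix(gt)
  if (!is.null(rownames(al$aligned)) && !is.null(rownames(G))) {
    G <- G[rownames(al$aligned), , drop = FALSE]
  }
  mean(sqrt(rowSums((al$aligned - G)^2)))
}

#' Frame-wise PA-MPJPE over a trajectory pair
#'
#' Frames that are invalid in either trajectory are skipped (counted in the
#' total only), mirroring the detected-frame bookkeeping of pose-estimation
#' benchmarks.
#'
#' @param pred,gt \code{\link{keypoint_trajectory}} objects over the same
#'   frames.
#' @param per_trial If \code{TRUE}, align once using all valid frames stacked
#'   (trial-level alignment) instead of per frame.
#' @return List with \code{per_frame_error} (mm, one per scored frame),
#'   \code{n_frames_scored} and \code{n_frames_total}.
#' @export
pa_mpjpe_trajectory <- function(pred, gt, per_trial = FALSE) {
  stopifnot(inherits(pred, "keypoint_trajectory"),
            inherits(gt, "keypoint_trajectory"))
  n <- dim(gt$positions)[1]
  if (dim(pred$positions)[1] != n) stopf("trajectories differ in length")
  ok <- pred$valid & gt$valid
  idx <- which(ok)
  if (length(idx) == 0L) stopf("no jointly valid frames to score")
  if (per_trial) {
    P <- do.call(rbind, lapply(idx, function(i) pos_frame(pred, i)))
    G <- do.call(rbind, lapply(idx, function(i) pos_frame(gt, i)))
    al <- procrustes_align(P, G)
    res <- sqrt(rowSums((al$aligned - G)^2))
    per_frame <- vapply(seq_along(idx), function(k) {
      mean(res[((k - 1L) * 7L + 1L):(k * 7L)])
    }, numeric(1))
  } else {
    per_frame <- vapply(idx, function(i) {
      pa_mpjpe_frame(pos_frame(pred, i), pos_frame(gt, i))
    }, numeric(1))
  }
  list(per_frame_error = per_frame, n_frames_scored = length(idx),
       n_frames_total = n)
}

#' Aggregate per-frame PA-MPJPE errors by stratum
#'
#' Summarizes scored trials as \code{mean +/- sd (n)} per stratum (e.g. video
#' resolution) plus an overall row. Empty strata are absent from the output
#' rather than reported as zero.
#'
#' @param errors List of numeric vectors of per-frame errors (one per trial),
#'   or a single numeric vector.
#' @param strata Optional factor/character stratum per trial.
#' @param totals Optional integer total frame counts per trial (defaults to
#'   the scored counts).
#' @return Data frame with columns \code{stratum, mean, sd, n_frames_scored,
#'   n_frames_total} (class \code{pa_mpjpe_summary}).
#' @export
pa_mpjpe_aggregate <- function(errors, strata = NULL, totals = NULL) {
  if (is.numeric(errors)) errors <- list(errors)
  if (length(errors) == 0L || sum(lengths(errors)) == 0L) {
    stopf("at least one scored frame is required")
  }
  if (is.null(strata)) strata <- rep("all", length(errors))
  if (is.null(totals)) totals <- lengths(errors)
  stopifnot(length(strata) == length(errors), length(totals) == length(errors))
  summarize <- function(sel, name) {
    e <- unlist(errors[sel], use.names = FALSE)
    if (length(e) == 0L) return(NULL)
    data.frame(stratum = name, mean = mean(e),
               sd = if (length(e) > 1L) sd(e) else 0,
               n_frames_scored = length(e),
               n_frames_total = sum(totals[sel]),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(unique(as.character(strata)), function(s) {
    summarize(which(as.character(strata) == s), s)
  })
  rows <- c(rows, list(summarize(seq_along(errors), "overall")))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  class(out) <- c("pa_mpjpe_summary", class(out))
  out
}

#' @export
print.pa_mpjpe_summary <- function(x, ...) {
  cat("<pa_mpjpe_summary> mean ± sd (n scored / n total) per stratum\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %.1f ± %.1f mm (%d / %d)\n", x$stratum[i],
                x$mean[i], x$sd[i], x$n_frames_scored[i], x$n_frames_total[i]))
  }
  invisible(x)
}
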