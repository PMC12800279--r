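# Kinematics: keypoint containers, marker reduction, camera-frame included
# angles, per-trial angle series and 101-point time normalization.

#' Joint-angle time series container
#'
#' Holds the four camera-frame flexion channels (\code{LHip, RHip, LKnee,
#' RKnee}) in degrees, one row per frame. Values are included angles, so 0
#' degrees denotes a fully extended segment chain and all values lie in
#' \eqn{[0, 180]}.
#'
#' @param angles Numeric n x 4 matrix (columns ordered as
#'   \code{\link{gait_channels}}; names optional).
#' @param fps Sampling rate, Hz.
#' @param trial_id,subject_id Identifiers.
#' @param label \code{"SCI"}, \code{"Healthy"} or \code{"unknown"}.
#' @param dropped_frames Integer indices of input frames excluded upstream.
#' @return An object of class \code{joint_angle_series}.
#' @export
joint_angle_series <- function(angles, fps = 50, trial_id = NA_character_,
                               subject_id = NA_character_, label = "unknown",
                               dropped_frames = integer()) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 4L) stopf("`angles` must have 4 channels")
  if (nrow(angles) < 1L) stopf("`angles` must have at least one frame")
  colnames(angles) <- gait_channels()
  if (any(!is.finite(angles))) stopf("angle values must be finite")
  if (any(angles < 0 | angles > 180)) {
    stopf("angle values must lie in [0, 180] degrees")
  }
  structure(list(angles = angles, fps = fps, trial_id = trial_id,
                 subject_id = subject_id, label = label,
                 dropped_frames = as.integer(dropped_frames)),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d frames @ %g Hz (%s, %s)\n",
              nrow(x$angles), x$fps, x$trial_id, x$label))
  rom <- channel_rom(x$angles)
  cat("  ROM (deg):", paste(sprintf("%s=%.1f", names(rom), rom),
                            collapse = " "), "\n")
  invisible(x)
}

# Accept joint_angle_series, normalized_cycle or bare matrix.
angle_matrix <- function(x) {
  m <- if (inherits(x, c("joint_angle_series", "normalized_cycle"))) {
    x$angles
  } else as.matrix(x)
  if (ncol(m) != 4L) stopf("expected 4 angle channels")
  colnames(m) <- gait_channels()
  m
}

replace_angles <- function(x, m) {
  if (inherits(x, c("joint_angle_series", "normalized_cycle"))) {
    x$angles <- m
    x
  } else m
}

#' 3D keypoint trajectory container
#'
#' @param positions Numeric array \code{n_frames x 3 x n_landmarks} with
#'   spatial dimensions named \code{x, y, z} (mm) and landmark names along the
#'   third dimension.
#' @param fps Sampling rate, Hz.
#' @param valid Logical per-frame validity flags; frames with missing
#'   coordinates in any required landmark default to invalid.
#' @param trial_id,subject_id,label Metadata.
#' @return An object of class \code{keypoint_trajectory}.
#' @export
keypoint_trajectory <- function(positions, fps = 50, valid = NULL,
                                trial_id = NA_character_,
                                subject_id = NA_character_,
                                label = "unknown") {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[2] == 3L)
  if (is.null(dimnames(positions)[[3]])) {
    stopf("`positions` must name its landmarks")
  }
  n <- dim(positions)[1]
  if (is.null(valid)) {
    required <- intersect(gait_landmarks(), dimnames(positions)[[3]])
    valid <- apply(positions[, , required, drop = FALSE], 1L,
                   function(f) all(is.finite(f)))
  }
  stopifnot(length(valid) == n)
  structure(list(positions = positions, fps = fps, valid = as.logical(valid),
                 trial_id = trial_id, subject_id = subject_id, label = label),
            class = "keypoint_trajectory")
}

#' @export
print.keypoint_trajectory <- function(x, ...) {
  cat(sprintf("<keypoint_trajectory> %d frames (%d valid), %d landmarks @ %g Hz\n",
              dim(x$positions)[1], sum(x$valid), dim(x$positions)[3], x$fps))
  invisible(x)
}

# Landmark x 3 matrix for one frame.
pos_frame <- function(traj, i) {
  m <- t(traj$positions[i, , ])
  colnames(m) <- c("x", "y", "z")
  m
}

#' Default 20-marker to 7-landmark reduction map
#'
#' The clinical motion-capture montage places 20 reflective markers on the
#' lower body; the pipeline works on 7 canonical landmarks obtained by
#' averaging marker groups. The exact montage differs between laboratories, so
#' this default (Plug-in-Gait-style names: pelvis cluster to Root, ASIS
#' markers to IAS, femoral condyle pairs to FLE, malleolus pairs to FAL) is a
#' documented, user-overridable assumption. Wand/heel markers present in the
#' montage but unused by any group are ignored.
#'
#' @return A named list mapping each of the 7 target landmarks to the marker
#'   names averaged into it (class \code{marker_reduction_map}).
#' @export
default_reduction_map <- function() {
  structure(list(
    Root  = c("SACR", "LPSI", "RPSI", "PELC"),
    IAS_L = "LASI",  IAS_R = "RASI",
    FLE_L = c("LLFC", "LMFC"), FLE_R = c("RLFC", "RMFC"),
    FAL_L = c("LLMA", "LMMA"), FAL_R = c("RLMA", "RMMA")),
    class = "marker_reduction_map")
}

#' Reduce a multi-marker trajectory to the 7 canonical landmarks
#'
#' Each target landmark is the arithmetic mean of the positions of its source
#' markers, frame by frame.
#'
#' @param traj A \code{\link{keypoint_trajectory}} containing all source
#'   markers named by \code{map}.
#' @param map Named list of target landmark -> source marker names; default
#'   \code{\link{default_reduction_map}}.
#' @return A \code{\link{keypoint_trajectory}} with exactly the 7 canonical
#'   landmarks.
#' @export
reduce_markers <- function(traj, map = default_reduction_map()) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  if (!setequal(names(map), gait_landmarks())) {
    stopf("`map` must define exactly the 7 canonical landmarks")
  }
  have <- dimnames(traj$positions)[[3]]
  missing <- setdiff(unique(unlist(map)), have)
  if (length(missing) > 0L) {
    stopf("source marker(s) missing from trajectory: %s",
          paste(missing, collapse = ", "))
  }
  n <- dim(traj$positions)[1]
  out <- array(NA_real_, dim = c(n, 3L, 7L),
               dimnames = list(NULL, c("x", "y", "z"), gait_landmarks()))
  for (target in gait_landmarks()) {
    src <- traj$positions[, , map[[target]], drop = FALSE]
    out[, , target] <- apply(src, c(1L, 2L), mean)
  }
  keypoint_trajectory(out, fps = traj$fps, trial_id = traj$trial_id,
                      subject_id = traj$subject_id, label = traj$label)
}

#' Included angle at a middle point, degrees
#'
#' The camera-frame flexion angle between the vectors
#' \code{a = p_prox - p_mid} and \code{b = p_mid - p_dist}:
#' \eqn{\theta = \arccos(a \cdot b / |a||b|)}. It is 0 when the three points
#' are collinear in order (fully extended chain) and lies in \eqn{[0, 180]}.
#'
#' @param p_prox,p_mid,p_dist 3-vectors (proximal, joint, distal), mm.
#' @return Angle in degrees.
#' @export
three_point_angle <- function(p_prox, p_mid, p_dist) {
  a <- as.numeric(p_prox) - as.numeric(p_mid)
  b <- as.numeric(p_mid) - as.numeric(p_dist)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) {
    stopf("degenerate landmark configuration: coincident points")
  }
  rad2deg(acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1)))
}

# Vectorized included angle over n x 3 point matrices.
included_angle_rows <- function(P, M, D) {
  a <- P - M
  b <- M - D
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  rad2deg(acos(pmin(pmax(rowSums(a * b) / (na * nb), -1), 1)))
}

#' Camera-frame hip/knee angle series from a keypoint trajectory
#'
#' Hip flexion is the included angle of the Root–IAS–FLE chain and knee
#' flexion of the IAS–FLE–FAL chain, per side, per frame. Invalid frames
#' (missing/non-finite landmarks) are dropped, not imputed; their input
#' indices are recorded in \code{dropped_frames}.
#'
#' @param traj A \code{\link{keypoint_trajectory}} with the 7 canonical
#'   landmarks.
#' @return A \code{\link{joint_angle_series}} with one row per valid frame.
#' @export
compute_angle_series <- function(traj) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  if (!all(gait_landmarks() %in% dimnames(traj$positions)[[3]])) {
    stopf("trajectory lacks canonical landmarks; apply reduce_markers() first")
  }
  keep <- which(traj$valid)
  if (length(keep) < 4L) {
    stopf("fewer than 4 valid frames: angle series unusable")
  }
  p <- function(lm) traj$positions[keep, , lm, drop = TRUE]
  m <- cbind(
    LHip  = included_angle_rows(p("Root"), p("IAS_L"), p("FLE_L")),
    RHip  = included_angle_rows(p("Root"), p("IAS_R"), p("FLE_R")),
    LKnee = included_angle_rows(p("IAS_L"), p("FLE_L"), p("FAL_L")),
    RKnee = included_angle_rows(p("IAS_R"), p("FLE_R"), p("FAL_R")))
  joint_angle_series(m, fps = traj$fps, trial_id = traj$trial_id,
                     subject_id = traj$subject_id, label = traj$label,
                     dropped_frames = setdiff(seq_len(dim(traj$positions)[1]),
                                              keep))
}

#' Normalized gait cycle container (101 samples per channel)
#'
#' @param angles 101 x 4 matrix, degrees; sample \code{i} corresponds to cycle
#'   position \code{(i - 1)\%}.
#' @param trial_id,subject_id,label Source trial metadata.
#' @return An object of class \code{normalized_cycle}.
#' @export
normalized_cycle <- function(angles, trial_id = NA_character_,
                             subject_id = NA_character_, label = "unknown") {
  angles <- as.matrix(angles)
  if (nrow(angles) != 101L || ncol(angles) != 4L) {
    stopf("a normalized cycle must be 101 x 4")
  }
  if (any(!is.finite(angles))) stopf("cycle values must be finite")
  colnames(angles) <- gait_channels()
  structure(list(angles = angles, trial_id = trial_id,
                 subject_id = subject_id, label = label),
            class = "normalized_cycle")
}

#' @export
print.normalized_cycle <- function(x, ...) {
  cat(sprintf("<normalized_cycle> 101 samples (%s, %s)\n", x$trial_id, x$label))
  invisible(x)
}

#' Normalize an angle series to the 101-point gait-cycle grid
#'
#' Maps a variable-length trial onto cycle positions 0–100. \code{"linear"}
#' interpolates piecewise-linearly at the 101 positions (used both for
#' upsampling short trials and downsampling long ones). \code{"block_average"}
#' averages the input frames falling into each of 101 equal-width bins
#' (nearest-percent assignment), filling empty bins by linear interpolation
#' between neighbouring non-empty bins — the averaging flavour of
#' downsampling.
#'
#' @param series A \code{\link{joint_angle_series}} (length >= 2).
#' @param method \code{"linear"} (default) or \code{"block_average"}.
#' @return A \code{\link{normalized_cycle}}.
#' @export
normalize_time <- function(series, method = c("linear", "block_average")) {
  method <- match.arg(method)
  m <- angle_matrix(series)
  n <- nrow(m)
  if (n < 2L) stopf("at least 2 frames are required for normalization")
  p <- seq(0, 1, length.out = n)
  q <- seq(0, 1, length.out = 101L)
  out <- if (method == "linear") {
    apply(m, 2L, function(v) approx(p, v, xout = q)$y)
  } else {
    bin <- as.integer(round(p * 100))
    apply(m, 2L, function(v) {
      means <- tapply(v, bin, mean)
      filled <- as.integer(names(means))
      approx(filled, as.numeric(means), xout = 0:100, rule = 2)$y
    })
  }
  meta <- if (inherits(series, "joint_angle_series")) {
    series[c("trial_id", "subject_id", "label")]
  } else list(trial_id = NA_character_, subject_id = NA_character_,
              label = "unknown")
  normalized_cycle(out, trial_id = meta$trial_id,
                   subject_id = meta$subject_id, label = meta$label)
}
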