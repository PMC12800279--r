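# Synthetic gait generator: parametric hip/knee flexion templates, pathology
# (ROM reduction + timing jitter), planar forward kinematics to 3D keypoints,
# and seeded two-class cohorts with hidden ground truth.

#' Parametric sagittal gait template
#'
#' Hip flexion is a raised cosine over the gait cycle; knee flexion is the sum
#' of two periodic Gaussian bumps (loading-response and swing peaks). Right
#' channels are the left channels evaluated half a cycle later (or at
#' \code{right_offset}). All angles are included angles in degrees, so 0 means
#' a fully extended (collinear) segment chain; defaults are chosen to resemble
#' normative sagittal gait curves while staying within the representable
#' \eqn{[0, 180]} degree range.
#'
#' @param hip_mean,hip_amp Mean and cosine amplitude of hip flexion (degrees).
#' @param hip_phase Cycle fraction in \code{[0, 1)} at which hip flexion peaks.
#' @param knee_bump1_amp,knee_bump1_center,knee_bump1_width First (stance) knee
#'   bump: amplitude (degrees), center and width (cycle fractions).
#' @param knee_bump2_amp,knee_bump2_center,knee_bump2_width Second (swing) knee
#'   bump.
#' @param right_offset Cycle fraction by which the right side lags the left
#'   (default 0.5, i.e. antiphase).
#' @return An object of class \code{gait_template_params}.
#' @export
gait_template_params <- function(hip_mean = 25, hip_amp = 20, hip_phase = 0,
                                 knee_bump1_amp = 18, knee_bump1_center = 0.15,
                                 knee_bump1_width = 0.08,
                                 knee_bump2_amp = 60, knee_bump2_center = 0.72,
                                 knee_bump2_width = 0.10,
                                 right_offset = 0.5) {
  check_number(hip_amp, "hip_amp", lower = 0)
  check_number(knee_bump1_amp, "knee_bump1_amp", lower = 0)
  check_number(knee_bump2_amp, "knee_bump2_amp", lower = 0)
  check_number(knee_bump1_width, "knee_bump1_width", lower = 0, closed_lower = FALSE)
  check_number(knee_bump2_width, "knee_bump2_width", lower = 0, closed_lower = FALSE)
  check_number(hip_phase, "hip_phase", lower = 0, upper = 1, closed_upper = FALSE)
  check_number(knee_bump1_center, "knee_bump1_center", lower = 0, upper = 1,
               closed_upper = FALSE)
  check_number(knee_bump2_center, "knee_bump2_center", lower = 0, upper = 1,
               closed_upper = FALSE)
  check_number(right_offset, "right_offset", lower = 0, upper = 1,
               closed_upper = FALSE)
  structure(list(hip_mean = hip_mean, hip_amp = hip_amp, hip_phase = hip_phase,
                 knee_bump1_amp = knee_bump1_amp,
                 knee_bump1_center = knee_bump1_center,
                 knee_bump1_width = knee_bump1_width,
                 knee_bump2_amp = knee_bump2_amp,
                 knee_bump2_center = knee_bump2_center,
                 knee_bump2_width = knee_bump2_width,
                 right_offset = right_offset),
            class = "gait_template_params")
}

#' Lower-body skeleton geometry
#'
#' Segment lengths used by the planar forward-kinematics model, in metres.
#'
#' @param pelvis_half_width Half distance between left and right IAS landmarks.
#' @param root_height_above_pelvis Vertical offset of the Root (body centre of
#'   gravity) above the IAS level.
#' @param thigh_length,shank_length Thigh (IAS to FLE) and shank (FLE to FAL)
#'   lengths.
#' @return An object of class \code{skeleton_geometry}.
#' @export
skeleton_geometry <- function(pelvis_half_width = 0.12,
                              root_height_above_pelvis = 0.10,
                              thigh_length = 0.42, shank_length = 0.43) {
  for (nm in c("pelvis_half_width", "root_height_above_pelvis",
               "thigh_length", "shank_length")) {
    check_number(get(nm), nm, lower = 0, closed_lower = FALSE)
  }
  structure(list(pelvis_half_width = pelvis_half_width,
                 root_height_above_pelvis = root_height_above_pelvis,
                 thigh_length = thigh_length, shank_length = shank_length),
            class = "skeleton_geometry")
}

#' Cohort generation settings
#'
#' Defines the study conditions emulated by \code{\link{generate_cohort}}: a
#' two-class (SCI / Healthy) cohort of variable-length trials with
#' class-dependent range-of-motion (ROM) reduction, additive angle and keypoint
#' noise, and a fraction of direction-reversed trials (recording artifacts
#' where the subject walked across the field of view the other way).
#'
#' @param n_per_class Number of trials per class.
#' @param rom_scale_sci ROM scaling factor(s) in \code{(0, 1]} applied to SCI
#'   trials; scalar or length-4 vector ordered as \code{\link{gait_channels}}.
#' @param frame_count_range Integer range \code{c(min, max)} of frames per
#'   trial (minimum 4).
#' @param fps Sampling rate, Hz.
#' @param angle_noise_sd Additive Gaussian noise on joint angles, degrees.
#' @param keypoint_noise_sd Additive Gaussian noise on keypoints, mm.
#' @param reversed_fraction Probability that a trial is direction-reversed.
#' @param timing_jitter_sd Smooth time-warp amplitude, cycle fraction.
#' @param walk_speed Forward walking speed, m/s.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_class = 40, rom_scale_sci = 0.5,
                          frame_count_range = c(60L, 250L), fps = 50,
                          angle_noise_sd = 2, keypoint_noise_sd = 2,
                          reversed_fraction = 0.3, timing_jitter_sd = 0.02,
                          walk_speed = 1.2, seed = 1L) {
  check_number(n_per_class, "n_per_class", lower = 1)
  if (!is.numeric(rom_scale_sci) || !length(rom_scale_sci) %in% c(1L, 4L) ||
      any(rom_scale_sci <= 0 | rom_scale_sci > 1)) {
    stopf("`rom_scale_sci` must be 1 or 4 factors in (0, 1]")
  }
  if (length(frame_count_range) != 2L || frame_count_range[1] < 4 ||
      frame_count_range[2] < frame_count_range[1]) {
    stopf("`frame_count_range` must be c(min, max) with min >= 4")
  }
  check_number(fps, "fps", lower = 0, closed_lower = FALSE)
  check_number(angle_noise_sd, "angle_noise_sd", lower = 0)
  check_number(keypoint_noise_sd, "keypoint_noise_sd", lower = 0)
  check_number(reversed_fraction, "reversed_fraction", lower = 0, upper = 1)
  check_number(timing_jitter_sd, "timing_jitter_sd", lower = 0)
  check_number(walk_speed, "walk_speed", lower = 0, closed_lower = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 rom_scale_sci = rom_scale_sci,
                 frame_count_range = as.integer(frame_count_range), fps = fps,
                 angle_noise_sd = angle_noise_sd,
                 keypoint_noise_sd = keypoint_noise_sd,
                 reversed_fraction = reversed_fraction,
                 timing_jitter_sd = timing_jitter_sd, walk_speed = walk_speed,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Periodic Gaussian bump on the unit circle of cycle fractions.
periodic_bump <- function(s, amp, center, width) {
  d <- abs(s - center)
  d <- pmin(d, 1 - d)
  amp * exp(-0.5 * (d / width)^2)
}

#' Evaluate a gait template at given cycle positions
#'
#' @param params A \code{\link{gait_template_params}} object.
#' @param phases Nondecreasing cycle fractions in \code{[0, 1]}.
#' @param fps Sampling rate recorded in the output, Hz.
#' @param ... Metadata passed to \code{\link{joint_angle_series}} (trial_id,
#'   subject_id, label).
#' @return A \code{\link{joint_angle_series}} with one sample per phase.
#' @export
angle_template <- function(params, phases, fps = 50, ...) {
  stopifnot(inherits(params, "gait_template_params"))
  if (length(phases) == 0L) stopf("`phases` must be non-empty")
  if (any(!is.finite(phases)) || any(phases < 0 | phases > 1)) {
    stopf("`phases` must lie in [0, 1]")
  }
  if (is.unsorted(phases)) stopf("`phases` must be nondecreasing")
  left <- function(s) {
    hip <- params$hip_mean +
      params$hip_amp * cos(2 * pi * (s - params$hip_phase))
    knee <- periodic_bump(s, params$knee_bump1_amp, params$knee_bump1_center,
                          params$knee_bump1_width) +
      periodic_bump(s, params$knee_bump2_amp, params$knee_bump2_center,
                    params$knee_bump2_width)
    cbind(hip, knee)
  }
  l <- left(phases)
  r <- left((phases + params$right_offset) %% 1)
  m <- cbind(LHip = l[, 1], RHip = r[, 1], LKnee = l[, 2], RKnee = r[, 2])
  joint_angle_series(m, fps = fps, ...)
}

#' Apply SCI-like pathology to an angle series
#'
#' Per channel, range of motion is rescaled about the channel minimum:
#' \eqn{\theta' = \min(\theta) + f\,(\theta - \min(\theta))}, so the resulting
#' ROM is exactly \code{rom_scale} times the input ROM and the baseline
#' (minimum flexion) is preserved — emulating reduced peak flexion rather than
#' a shifted posture. An optional smooth, endpoint-preserving time warp adds
#' timing variability before the rescaling.
#'
#' @param series A \code{\link{joint_angle_series}} or an n x 4 angle matrix.
#' @param rom_scale Scaling factor(s) in \code{(0, 1]}; scalar or length 4
#'   (ordered as \code{\link{gait_channels}}).
#' @param timing_jitter_sd Standard deviation (cycle fraction) of the smooth
#'   time-warp coefficients; 0 disables the warp. Uses the current RNG stream.
#' @return Same type as the input.
#' @export
apply_pathology <- function(series, rom_scale, timing_jitter_sd = 0) {
  if (any(rom_scale <= 0 | rom_scale > 1)) {
    stopf("`rom_scale` must lie in (0, 1]")
  }
  if (!length(rom_scale) %in% c(1L, 4L)) {
    stopf("`rom_scale` must have length 1 or 4")
  }
  m <- angle_matrix(series)
  if (timing_jitter_sd > 0 && nrow(m) >= 3L) {
    p <- seq(0, 1, length.out = nrow(m))
    a <- max(min(rnorm(1, 0, timing_jitter_sd), 3 * timing_jitter_sd),
             -3 * timing_jitter_sd)
    b <- max(min(rnorm(1, 0, timing_jitter_sd / 2), 1.5 * timing_jitter_sd),
             -1.5 * timing_jitter_sd)
    # Keep the warp monotone: derivative perturbation bounded below 1.
    shrink <- max(1, (2 * pi * abs(a) + 4 * pi * abs(b)) / 0.9)
    a <- a / shrink; b <- b / shrink
    warped <- p + a * sin(2 * pi * p) + b * sin(4 * pi * p)
    m <- apply(m, 2L, function(v) approx(p, v, xout = warped, rule = 2)$y)
  }
  f <- rep(rom_scale, length.out = 4L)
  for (j in seq_len(4L)) {
    mn <- min(m[, j])
    m[, j] <- mn + f[j] * (m[, j] - mn)
  }
  replace_angles(series, m)
}

# Swap the two reflections used for direction-reversed trials.
mirror_landmark_names <- function(nms) {
  swapped <- nms
  swapped[nms == "IAS_L"] <- "IAS_R"; swapped[nms == "IAS_R"] <- "IAS_L"
  swapped[nms == "FLE_L"] <- "FLE_R"; swapped[nms == "FLE_R"] <- "FLE_L"
  swapped[nms == "FAL_L"] <- "FAL_R"; swapped[nms == "FAL_R"] <- "FAL_L"
  swapped
}

#' Planar forward kinematics: joint angles to 3D keypoints
#'
#' Builds a sagittal-plane skeleton whose included angles reproduce the input
#' channels by construction: the Root–IAS–FLE included angle equals the hip
#' channel and the IAS–FLE–FAL included angle equals the knee channel for each
#' side, for any angles in \eqn{[0, 180]} degrees. The Root translates forward
#' at \code{walk_speed}. Coordinates are right-handed millimetres with +x the
#' walking direction, +y up and +z mediolateral. \code{direction = "-x"}
#' emulates a direction-reversed recording: the trajectory is rotated half a
#' turn about the vertical axis and the left/right landmark labels are
#' swapped, so recovered angle channels appear left/right exchanged.
#'
#' @param angles A \code{\link{joint_angle_series}} or n x 4 matrix, degrees.
#' @param geom A \code{\link{skeleton_geometry}}.
#' @param walk_speed Forward speed, m/s.
#' @param direction \code{"+x"} (default) or \code{"-x"}.
#' @param fps Sampling rate, Hz (taken from the series if available).
#' @return A \code{\link{keypoint_trajectory}} with the 7 canonical landmarks.
#' @export
forward_kinematics <- function(angles, geom = skeleton_geometry(),
                               walk_speed = 1.2, direction = c("+x", "-x"),
                               fps = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(geom, "skeleton_geometry"))
  m <- angle_matrix(angles)
  if (any(!is.finite(m))) stopf("angles must be finite")
  if (is.null(fps)) {
    fps <- if (inherits(angles, "joint_angle_series")) angles$fps else 50
  }
  n <- nrow(m)
  w <- geom$pelvis_half_width * 1000
  rh <- geom$root_height_above_pelvis * 1000
  thigh <- geom$thigh_length * 1000
  shank <- geom$shank_length * 1000
  y0 <- (geom$thigh_length + geom$shank_length) * 1000
  pos <- array(NA_real_, dim = c(n, 3L, 7L),
               dimnames = list(NULL, c("x", "y", "z"), gait_landmarks()))
  x0 <- walk_speed * 1000 * (seq_len(n) - 1L) / fps
  pos[, , "Root"] <- cbind(x0, y0 + rh, 0)
  for (side in c("L", "R")) {
    sz <- if (side == "L") 1 else -1
    th <- deg2rad(m[, paste0(side, "Hip")])
    tk <- deg2rad(m[, paste0(side, "Knee")])
    ias <- cbind(x0, y0, sz * w)
    # In-plane basis: u points from IAS to Root (no x component), v = +x.
    un <- sqrt(rh^2 + w^2)
    u <- c(0, rh, -sz * w) / un
    d <- cbind(sin(th), -cos(th) * u[2], -cos(th) * u[3])
    fle <- ias + thigh * d
    e <- cbind(sin(th - tk), -cos(th - tk) * u[2], -cos(th - tk) * u[3])
    fal <- fle + shank * e
    pos[, , paste0("IAS_", side)] <- ias
    pos[, , paste0("FLE_", side)] <- fle
    pos[, , paste0("FAL_", side)] <- fal
  }
  if (direction == "-x") {
    pos[, c(1L, 3L), ] <- -pos[, c(1L, 3L), ]
    dimnames(pos)[[3]] <- mirror_landmark_names(dimnames(pos)[[3]])
    pos <- pos[, , gait_landmarks(), drop = FALSE]
  }
  meta <- if (inherits(angles, "joint_angle_series")) {
    angles[c("trial_id", "subject_id", "label")]
  } else list(trial_id = NA_character_, subject_id = NA_character_,
              label = "unknown")
  keypoint_trajectory(pos, fps = fps, trial_id = meta$trial_id,
                      subject_id = meta$subject_id, label = meta$label)
}

#' Generate a labelled two-class synthetic gait cohort
#'
#' Produces \code{n_per_class} Healthy and \code{n_per_class} SCI trials. Each
#' trial samples one gait cycle at a random frame count, applies a smooth
#' timing warp, SCI trials additionally receive the configured ROM reduction,
#' Gaussian angle noise (clamped to the representable \eqn{[0, 180]} degrees)
#' is added, the skeleton is rendered through
#' \code{\link{forward_kinematics}} (a random subset of trials
#' direction-reversed), and Gaussian keypoint noise is added. The hidden
#' ground truth (reversal flag, ROM scale, clean angles) is attached to each
#' trial for downstream validation. Fully reproducible from
#' \code{config$seed}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param params A \code{\link{gait_template_params}}.
#' @param geom A \code{\link{skeleton_geometry}}.
#' @return A list of trials (class \code{gait_cohort}); each trial holds
#'   \code{keypoints}, \code{label}, \code{subject_id}, \code{trial_id},
#'   \code{fps} and a \code{truth} list.
#' @export
generate_cohort <- function(config = cohort_config(),
                            params = gait_template_params(),
                            geom = skeleton_geometry()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    trials <- vector("list", 2L * config$n_per_class)
    idx <- 0L
    for (label in c("Healthy", "SCI")) {
      for (i in seq_len(config$n_per_class)) {
        idx <- idx + 1L
        subject <- sprintf("%s%03d", if (label == "SCI") "P" else "H", i)
        trial_id <- paste0(subject, "_T1")
        n <- sample(seq.int(config$frame_count_range[1],
                            config$frame_count_range[2]), 1L)
        ser <- angle_template(params, seq(0, 1, length.out = n),
                              fps = config$fps, trial_id = trial_id,
                              subject_id = subject, label = label)
        rom_scale <- if (label == "SCI") config$rom_scale_sci else 1
        ser <- apply_pathology(ser, rom_scale, config$timing_jitter_sd)
        clean <- ser$angles
        noisy <- clean + matrix(rnorm(length(clean), 0, config$angle_noise_sd),
                                nrow = nrow(clean))
        ser$angles <- pmin(pmax(noisy, 0), 180)
        reversed <- runif(1) < config$reversed_fraction
        traj <- forward_kinematics(ser, geom, config$walk_speed,
                                   direction = if (reversed) "-x" else "+x")
        traj$positions <- traj$positions +
          array(rnorm(length(traj$positions), 0, config$keypoint_noise_sd),
                dim = dim(traj$positions))
        trials[[idx]] <- structure(
          list(keypoints = traj, label = label, subject_id = subject,
               trial_id = trial_id, fps = config$fps,
               truth = list(reversed = reversed, rom_scale = rom_scale,
                            clean_angles = clean)),
          class = "gait_trial")
      }
    }
    structure(trials, class = "gait_cohort", config = config,
              params = params, geom = geom)
  })
}

# Uniform random proper rotation (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3L, 3L))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a ground-truth / prediction trajectory pair for benchmarking
#'
#' The predicted trajectory is a frame-wise similarity transform of the truth
#' (\code{pred = scale * truth \%*\% t(rotation) + translation}) plus optional
#' isotropic Gaussian noise — a controlled fixture for Procrustes-aligned
#' error metrics.
#'
#' @param n_frames Number of frames.
#' @param rotation 3 x 3 proper rotation matrix, or \code{NULL} for a random
#'   one.
#' @param translation Length-3 translation, mm.
#' @param scale Positive scale factor.
#' @param noise_sd Keypoint noise on the prediction, mm.
#' @param params,geom Template and geometry for the underlying gait.
#' @return List with elements \code{gt}, \code{pred} (both
#'   \code{\link{keypoint_trajectory}}) and \code{transform}.
#' @export
generate_benchmark_pair <- function(n_frames, rotation = NULL,
                                    translation = c(0, 0, 0), scale = 1,
                                    noise_sd = 0,
                                    params = gait_template_params(),
                                    geom = skeleton_geometry()) {
  check_number(scale, "scale", lower = 0, closed_lower = FALSE)
  check_number(n_frames, "n_frames", lower = 1)
  if (is.null(rotation)) rotation <- random_rotation()
  stopifnot(is.matrix(rotation), all(dim(rotation) == 3L))
  ser <- angle_template(params, seq(0, 1, length.out = n_frames))
  gt <- forward_kinematics(ser, geom)
  pred <- gt
  for (i in seq_len(n_frames)) {
    x <- pos_frame(gt, i)                          # 7 x 3
    y <- scale * x %*% t(rotation) +
      matrix(translation, nrow(x), 3L, byrow = TRUE)
    if (noise_sd > 0) y <- y + matrix(rnorm(length(y), 0, noise_sd), nrow(x))
    pred$positions[i, , ] <- t(y)
  }
  list(gt = gt, pred = pred,
       transform = list(rotation = rotation, translation = translation,
                        scale = scale, noise_sd = noise_sd))
}
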