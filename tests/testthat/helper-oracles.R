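# Independent oracles and fixture builders used across the suite. Oracles are
# deliberately naive (enumeration, closed forms, generic optimizers) and never
# share code with the implementation they check.

# DTW by exhaustive enumeration of all monotone warping paths (univariate,
# absolute pointwise distance). Feasible for n * m up to ~25.
bf_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (acc > best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, acc)
    if (i < n) rec(i + 1L, j, acc)
    if (j < m) rec(i, j + 1L, acc)
  }
  rec(1L, 1L, 0)
  best
}

channel_rom_test <- function(m) apply(m, 2L, function(v) max(v) - min(v))

# Included angle via atan2 of cross/dot products.
atan2_angle <- function(p, m, d) {
  a <- p - m; b <- m - d
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
}

# Rotation matrix from Euler angles (Z-Y-X convention).
euler_rotation <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3,
               byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Rotation matrix from an (unnormalized) quaternion; normalization happens
# inside, so the parameterization is smooth over R^4 \ {0} and free of the
# gimbal degeneracies of Euler angles.
quaternion_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Minimum alignment residual (root summed squared distance, mm) over
# similarity transforms, found by a generic numeric optimizer: multi-start
# BFGS over a quaternion rotation, with scale and per-axis translation
# profiled out by an ordinary least-squares fit at every candidate rotation —
# independent of the closed-form alignment.
optimizer_align_residual <- function(P, G, n_starts = 12) {
  n <- nrow(P)
  Pc <- sweep(P, 2L, colMeans(P))
  Gc <- sweep(G, 2L, colMeans(G))
  y <- as.vector(Gc)
  axis <- rep(seq_len(3L), each = n)
  obj <- function(q) {
    Z <- Pc %*% t(quaternion_rotation(q))
    X <- cbind(as.vector(Z), axis == 1, axis == 2, axis == 3)
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  starts <- c(list(c(1, 0, 0, 0)),
              lapply(seq_len(n_starts - 1), function(i) rnorm(4)))
  best <- Inf
  for (q0 in starts) {
    fit <- optim(q0, obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-16))
    fit <- optim(fit$par, obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-16))
    if (fit$value < best) best <- fit$value
  }
  sqrt(best)
}

# Apply a similarity transform to the rows of an n x 3 matrix.
similarity_transform <- function(X, R, s = 1, t = c(0, 0, 0)) {
  sweep(s * X %*% t(R), 2L, t, `+`)
}

# Random template whose angles stay inside [0, 180] degrees.
random_template <- function() {
  hip_mean <- runif(1, 10, 40)
  gait_template_params(
    hip_mean = hip_mean, hip_amp = runif(1, 0, hip_mean),
    hip_phase = runif(1, 0, 0.99),
    knee_bump1_amp = runif(1, 0, 40), knee_bump1_center = runif(1, 0, 0.99),
    knee_bump1_width = runif(1, 0.05, 0.2),
    knee_bump2_amp = runif(1, 0, 70), knee_bump2_center = runif(1, 0, 0.99),
    knee_bump2_width = runif(1, 0.05, 0.2),
    right_offset = runif(1, 0, 0.99))
}

# A 101 x 4 template cycle matrix (noise added by callers).
template_cycle <- function(params = gait_template_params()) {
  angle_template(params, seq(0, 1, length.out = 101))$angles
}

# Linearly separable cohort: the classes differ by a constant offset on every
# feature, far beyond the noise level.
make_shift_cohort <- function(n_per_class = 25, delta = 8, noise_sd = 2) {
  base <- template_cycle()
  build <- function(label, off) {
    lapply(seq_len(n_per_class), function(i) {
      m <- base + off + matrix(rnorm(404, 0, noise_sd), 101, 4)
      normalized_cycle(pmin(pmax(m, 0), 180),
                       trial_id = sprintf("%s%03d", label, i), label = label)
    })
  }
  list(cycles = c(build("Healthy", 0), build("SCI", delta)),
       labels = rep(c("Healthy", "SCI"), each = n_per_class))
}

# Cohort of normalized cycles where the classes differ only on one channel
# over one cycle-percent window: the localization fixture for attribution.
make_window_cohort <- function(n_per_class = 30, channel = "LKnee",
                               window = c(40, 60), delta = 10, noise_sd = 2) {
  base <- template_cycle()
  build <- function(label, shift) {
    lapply(seq_len(n_per_class), function(i) {
      m <- base + matrix(rnorm(404, 0, noise_sd), 101, 4)
      if (shift) {
        rows <- (window[1] + 1):(window[2] + 1)
        m[rows, channel] <- m[rows, channel] + delta
      }
      normalized_cycle(pmin(pmax(m, 0), 180),
                       trial_id = sprintf("%s%03d", label, i), label = label)
    })
  }
  cycles <- c(build("Healthy", FALSE), build("SCI", TRUE))
  list(cycles = cycles,
       labels = rep(c("Healthy", "SCI"), each = n_per_class))
}

# 20-marker trajectory whose group means reproduce a 7-landmark trajectory.
make_20_marker_trajectory <- function(traj7) {
  map <- default_reduction_map()
  n <- dim(traj7$positions)[1]
  montage <- c(unlist(map, use.names = FALSE),
               "LTHI", "RTHI", "LTIB", "RTIB", "LHEE", "RHEE")
  pos <- array(NA_real_, dim = c(n, 3L, length(montage)),
               dimnames = list(NULL, c("x", "y", "z"), montage))
  for (target in names(map)) {
    src <- map[[target]]
    k <- length(src)
    # Offsets around the target that cancel in the mean.
    offs <- matrix(rnorm(3 * k, 0, 15), k, 3)
    offs <- sweep(offs, 2L, colMeans(offs))
    for (i in seq_len(k)) {
      pos[, , src[i]] <- traj7$positions[, , target] +
        matrix(offs[i, ], n, 3, byrow = TRUE)
    }
  }
  for (extra in c("LTHI", "RTHI", "LTIB", "RTIB", "LHEE", "RHEE")) {
    pos[, , extra] <- matrix(rnorm(3 * n, 0, 500), n, 3)
  }
  keypoint_trajectory(pos, fps = traj7$fps, valid = traj7$valid,
                      trial_id = traj7$trial_id)
}
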