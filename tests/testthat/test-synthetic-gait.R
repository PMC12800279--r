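# Synthetic gait generator: template evaluation, pathology scaling, forward
# kinematics, cohort generation and benchmark fixtures.

test_that("constant template and phase-offset symmetry hold", {
  flat <- gait_template_params(hip_mean = 10, hip_amp = 0,
                               knee_bump1_amp = 0, knee_bump2_amp = 0)
  ser <- angle_template(flat, seq(0, 1, length.out = 20))
  expect_true(all(ser$angles[, c("LHip", "RHip")] == 10))
  expect_true(all(ser$angles[, c("LKnee", "RKnee")] == 0))

  ser <- angle_template(gait_template_params(), c(0, 0.5))
  expect_equal(unname(ser$angles[1, "RHip"]), unname(ser$angles[2, "LHip"]))
  expect_equal(unname(ser$angles[1, "RKnee"]), unname(ser$angles[2, "LKnee"]))

  expect_error(angle_template(gait_template_params(), numeric()), "non-empty")
  expect_error(angle_template(gait_template_params(), c(0.5, 0.2)),
               "nondecreasing")
})

test_that("knee ROM matches a dense-grid brute-force bump evaluation", {
  p <- gait_template_params()
  s <- seq(0, 1, length.out = 20001)
  # Independent re-evaluation of the two periodic bell bumps.
  bump <- function(s, amp, cen, w) {
    d <- pmin(abs(s - cen), 1 - abs(s - cen))
    amp * exp(-0.5 * (d / w)^2)
  }
  knee <- bump(s, p$knee_bump1_amp, p$knee_bump1_center, p$knee_bump1_width) +
    bump(s, p$knee_bump2_amp, p$knee_bump2_center, p$knee_bump2_width)
  ser <- angle_template(p, s)
  expect_equal(max(ser$angles[, "LKnee"]) - min(ser$angles[, "LKnee"]),
               max(knee) - min(knee), tolerance = 1e-12)
})

test_that("pathology scaling is exact about the channel minimum", {
  ser <- angle_template(gait_template_params(), seq(0, 1, length.out = 80))
  expect_equal(apply_pathology(ser, 1)$angles, ser$angles)

  half <- apply_pathology(ser, 0.5)
  expect_equal(apply(half$angles, 2, min), apply(ser$angles, 2, min))
  expect_equal(channel_rom_test(half$angles), 0.5 * channel_rom_test(ser$angles))

  # Property over random templates and scale factors.
  set.seed(11)
  for (i in 1:20) {
    p <- random_template()
    ser <- angle_template(p, seq(0, 1, length.out = sample(30:120, 1)))
    f <- runif(1, 0.1, 1)
    out <- apply_pathology(ser, f)
    expect_equal(channel_rom_test(out$angles), f * channel_rom_test(ser$angles),
                 tolerance = 1e-9)
  }
  expect_error(apply_pathology(ser, 0), "\\(0, 1\\]")
  expect_error(apply_pathology(ser, 1.2), "\\(0, 1\\]")
})

test_that("straight legs give collinear landmark chains", {
  m <- matrix(0, 10, 4)
  traj <- forward_kinematics(m)
  for (i in c(1, 5, 10)) {
    f <- gaitsig:::pos_frame(traj, i)
    for (side in c("L", "R")) {
      hip <- three_point_angle(f["Root", ], f[paste0("IAS_", side), ],
                               f[paste0("FLE_", side), ])
      knee <- three_point_angle(f[paste0("IAS_", side), ],
                                f[paste0("FLE_", side), ],
                                f[paste0("FAL_", side), ])
      expect_lt(hip, 1e-6)
      expect_lt(knee, 1e-6)
    }
  }
  expect_error(forward_kinematics(matrix(c(NA, 1, 1, 1), 1)), "finite")
})

test_that("angle recovery inverts forward kinematics and mirroring", {
  set.seed(21)
  for (i in 1:10) {
    ser <- angle_template(random_template(),
                          seq(0, 1, length.out = sample(20:60, 1)))
    rec <- compute_angle_series(forward_kinematics(ser))
    expect_equal(rec$angles, ser$angles, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # Mirror consistency: reversed direction swaps the recovered channels.
    rev <- compute_angle_series(forward_kinematics(ser, direction = "-x"))
    expect_equal(rev$angles[, c("RHip", "LHip", "RKnee", "LKnee")],
                 ser$angles, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("cohorts have the configured size, reversal rate and determinism", {
  cfg <- cohort_config(n_per_class = 3, reversed_fraction = 0, seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co, 6L)
  expect_false(any(vapply(co, function(t) t$truth$reversed, logical(1))))
  expect_equal(sum(vapply(co, function(t) t$label, character(1)) == "SCI"), 3L)

  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)

  # Observed reversal share within the binomial 99% interval of 0.3.
  cfg <- cohort_config(n_per_class = 150, frame_count_range = c(10, 20),
                       reversed_fraction = 0.3, seed = 9)
  co <- generate_cohort(cfg)
  n_rev <- sum(vapply(co, function(t) t$truth$reversed, logical(1)))
  band <- qbinom(c(0.005, 0.995), 300, 0.3)
  expect_gte(n_rev, band[1])
  expect_lte(n_rev, band[2])
})

test_that("benchmark pairs behave under similarity transforms and noise", {
  set.seed(31)
  pair <- generate_benchmark_pair(5, scale = 1.7,
                                  translation = c(100, -50, 20))
  res <- pa_mpjpe_trajectory(pair$pred, pair$gt)
  expect_true(all(res$per_frame_error < 1e-9))

  ident <- generate_benchmark_pair(4, rotation = diag(3))
  expect_equal(ident$pred$positions, ident$gt$positions)

  # Mean error grows monotonically with the noise level.
  errs <- vapply(c(1, 5, 25), function(sigma) {
    p <- generate_benchmark_pair(40, noise_sd = sigma)
    mean(pa_mpjpe_trajectory(p$pred, p$gt)$per_frame_error)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_error(generate_benchmark_pair(5, scale = -1), "range")
})
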