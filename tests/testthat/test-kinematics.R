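# Marker reduction, included angles, angle series and time normalization.

test_that("marker reduction averages groups and yields the 7 landmarks", {
  ser <- angle_template(gait_template_params(), seq(0, 1, length.out = 30))
  traj7 <- forward_kinematics(ser)
  set.seed(41)
  traj20 <- make_20_marker_trajectory(traj7)
  expect_equal(dim(traj20$positions)[3], 20L)

  red <- reduce_markers(traj20)
  expect_setequal(dimnames(red$positions)[[3]], gait_landmarks())
  expect_equal(dim(red$positions)[3], 7L)
  expect_equal(red$positions[, , gait_landmarks()],
               traj7$positions[, , gait_landmarks()], tolerance = 1e-9)

  # Identity grouping: every target fed by a single marker at itself.
  id_map <- structure(as.list(gait_landmarks()), names = gait_landmarks(),
                      class = "marker_reduction_map")
  red_id <- reduce_markers(traj7, id_map)
  expect_equal(red_id$positions, traj7$positions)

  # Midpoint of a two-marker group.
  two <- traj20
  two$positions[, , "LLMA"] <- 0
  two$positions[, , "LMMA"] <- matrix(c(2, 0, 0), 30, 3, byrow = TRUE)
  red2 <- reduce_markers(two)
  expect_equal(unname(red2$positions[1, , "FAL_L"]), c(1, 0, 0))

  bad <- default_reduction_map()
  bad$Root <- c("SACR", "NOPE")
  expect_error(reduce_markers(traj20, bad), "NOPE")
})

test_that("three-point angle matches hand cases and the atan2 oracle", {
  expect_equal(three_point_angle(c(0, 2, 0), c(0, 1, 0), c(0, 0, 0)), 0)
  expect_equal(three_point_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 90)
  expect_error(three_point_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")

  set.seed(42)
  for (i in 1:50) {
    p <- rnorm(3); m <- rnorm(3); d <- rnorm(3)
    expect_equal(three_point_angle(p, m, d), atan2_angle(p, m, d),
                 tolerance = 1e-9)
  }
})

test_that("three-point angle is invariant to common similarity transforms", {
  set.seed(43)
  for (i in 1:25) {
    pts <- matrix(rnorm(9, sd = 100), 3, 3)
    base <- three_point_angle(pts[1, ], pts[2, ], pts[3, ])
    R <- euler_rotation(runif(1, -pi, pi), runif(1, -pi, pi),
                        runif(1, -pi, pi))
    s <- runif(1, 0.1, 10)
    t <- rnorm(3, sd = 50)
    moved <- similarity_transform(pts, R, s, t)
    expect_equal(three_point_angle(moved[1, ], moved[2, ], moved[3, ]),
                 base, tolerance = 1e-9)
  }
})

test_that("angle series drops invalid frames and demands enough of them", {
  ser <- angle_template(gait_template_params(), seq(0, 1, length.out = 12))
  traj <- forward_kinematics(ser)
  traj$valid[c(3, 7)] <- FALSE
  rec <- compute_angle_series(traj)
  expect_equal(nrow(rec$angles), 10L)
  expect_equal(rec$dropped_frames, c(3L, 7L))
  expect_equal(rec$angles, ser$angles[-c(3, 7), ], tolerance = 1e-6,
               ignore_attr = TRUE)

  traj$valid[] <- FALSE
  traj$valid[1:3] <- TRUE
  expect_error(compute_angle_series(traj), "fewer than 4")

  flat <- forward_kinematics(matrix(0, 8, 4))
  rec0 <- compute_angle_series(flat)
  expect_true(all(rec0$angles < 1e-6))
})

test_that("time normalization always lands on the 101-point grid", {
  for (n in c(37, 101, 250)) {
    ser <- angle_template(gait_template_params(), seq(0, 1, length.out = n))
    for (method in c("linear", "block_average")) {
      cyc <- normalize_time(ser, method = method)
      expect_equal(dim(cyc$angles), c(101L, 4L))
      expect_true(all(is.finite(cyc$angles)))
    }
  }
})

test_that("linear normalization is exact on identities and ramps", {
  ser <- angle_template(gait_template_params(), seq(0, 1, length.out = 101))
  expect_equal(normalize_time(ser)$angles, ser$angles, ignore_attr = TRUE)

  ramp <- joint_angle_series(matrix(seq(0, 50, length.out = 51), 51, 4))
  cyc <- normalize_time(ramp)
  expect_equal(cyc$angles[, 1], 50 * (0:100) / 100)

  # Monotone segments keep their endpoints, hence channel min and max.
  expect_equal(min(cyc$angles), 0)
  expect_equal(max(cyc$angles), 50)

  expect_error(normalize_time(joint_angle_series(matrix(1, 1, 4))),
               "at least 2")
})

test_that("block-average normalization averages within bins", {
  # 201 frames: each percent bin receives exactly two interior frames.
  v <- seq(0, 100, length.out = 201)
  ser <- joint_angle_series(matrix(v, 201, 4))
  cyc <- normalize_time(ser, method = "block_average")
  bins <- as.integer(round(seq(0, 1, length.out = 201) * 100))
  expected <- as.numeric(tapply(v, bins, mean))
  expect_equal(cyc$angles[, 2], expected)
})
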