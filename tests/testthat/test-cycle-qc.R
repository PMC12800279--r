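# Cycle quality control: clustering, reversed-cluster detection, flipping and
# subset construction.

noisy_cycles <- function(base, n, sd = 2, prefix = "t", swap = FALSE) {
  lapply(seq_len(n), function(i) {
    m <- base + matrix(rnorm(404, 0, sd), 101, 4)
    if (swap) m <- m[, c("RHip", "LHip", "RKnee", "LKnee")]
    colnames(m) <- gait_channels()
    normalized_cycle(pmin(pmax(m, 0), 180),
                     trial_id = sprintf("%s%03d", prefix, i))
  })
}

test_that("k = 1 gives the grand mean and duplicates give zero inertia", {
  set.seed(61)
  base <- template_cycle()
  cyc <- noisy_cycles(base, 8)
  m1 <- cluster_cycles(cyc, k = 1, seed = 1)
  grand <- Reduce(`+`, lapply(cyc, function(c) c$angles)) / 8
  expect_equal(gaitsig:::unflatten_cycle(m1$centroids[1, ]), grand,
               tolerance = 1e-9, ignore_attr = TRUE)

  dup <- rep(noisy_cycles(base, 1), 5)
  m0 <- cluster_cycles(dup, k = 1, seed = 1)
  expect_equal(m0$inertia, 0, tolerance = 1e-9)

  expect_error(cluster_cycles(cyc, k = 20), "at least")
})

test_that("well-separated groups are recovered up to relabelling", {
  set.seed(62)
  base <- template_cycle()
  g1 <- noisy_cycles(base, 12, sd = 1, prefix = "a")
  g2 <- noisy_cycles(base + 40, 10, sd = 1, prefix = "b")
  model <- cluster_cycles(c(g1, g2), k = 2, seed = 7)
  a <- model$assignments
  expect_length(unique(a[1:12]), 1L)
  expect_length(unique(a[13:22]), 1L)
  expect_true(a[1] != a[13])
  # Each centroid is the mean of its members.
  X <- t(vapply(c(g1, g2), gaitsig:::flatten_cycle, numeric(404)))
  for (j in 1:2) {
    expect_equal(model$centroids[j, ],
                 colMeans(X[a == j, , drop = FALSE]), tolerance = 1e-6)
  }
})

test_that("clustering is seed-deterministic with non-increasing inertia", {
  set.seed(63)
  cyc <- noisy_cycles(template_cycle(), 20, sd = 8)
  m1 <- cluster_cycles(cyc, k = 4, seed = 3)
  m2 <- cluster_cycles(cyc, k = 4, seed = 3)
  expect_identical(m1$assignments, m2$assignments)
  expect_identical(m1$centroids, m2$centroids)
  expect_true(all(diff(m1$inertia_trace) <= 1e-9))
})

test_that("lloyd refinement agrees with stats::kmeans from shared centers", {
  set.seed(64)
  base <- template_cycle()
  cyc <- c(noisy_cycles(base, 10, sd = 2, prefix = "a"),
           noisy_cycles(base + 25, 10, sd = 2, prefix = "b"))
  X <- t(vapply(cyc, gaitsig:::flatten_cycle, numeric(404)))
  init <- gaitsig:::with_seed(5, gaitsig:::kmeanspp_init(X, 2))
  mine <- cluster_cycles(cyc, k = 2, seed = 5)
  ref <- stats::kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd")
  expect_equal(sort(mine$sizes), sort(as.integer(ref$size)))
  expect_equal(mine$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("flip is an involution and leaves symmetric cycles unchanged", {
  set.seed(65)
  cyc <- noisy_cycles(template_cycle(), 1)[[1]]
  expect_equal(flip_trial(flip_trial(cyc)), cyc)

  sym <- cyc
  sym$angles[, "RHip"] <- sym$angles[, "LHip"]
  sym$angles[, "RKnee"] <- sym$angles[, "LKnee"]
  expect_equal(flip_trial(sym), sym)

  tr <- flip_trial(cyc, mode = "time_reverse")
  expect_equal(unname(tr$angles[1, "LHip"]), unname(cyc$angles[101, "RHip"]))
})

test_that("mirrored clusters are detected and flipping restores the twin", {
  set.seed(66)
  base <- template_cycle()
  normal <- noisy_cycles(base, 14, sd = 2, prefix = "n")
  mirrored <- noisy_cycles(base, 6, sd = 2, prefix = "m", swap = TRUE)
  model <- cluster_cycles(c(normal, mirrored), k = 2, seed = 11)
  typical <- select_typical_cluster(model)
  rev <- detect_reversed_clusters(model, typical)
  expect_length(rev, 1L)
  expect_setequal(names(model$assignments)[model$assignments == rev],
                  sprintf("m%03d", 1:6))
  # The centroid equal to the reference itself is never flagged.
  expect_false(typical %in% rev)
  # Flipping a mirrored trial matches its unmirrored construction (noise-level).
  flipped <- flip_trial(mirrored[[1]])
  expect_lt(max(abs(flipped$angles - base)), 10)
  expect_gt(max(abs(mirrored[[1]]$angles - base)), 20)
})

test_that("an exactly mirrored centroid is flagged, an identical one is not", {
  set.seed(67)
  base <- template_cycle()
  model <- cluster_cycles(c(noisy_cycles(base, 3, sd = 0.01, prefix = "a"),
                            noisy_cycles(base, 3, sd = 0.01, prefix = "b",
                                         swap = TRUE),
                            noisy_cycles(base, 3, sd = 0.01, prefix = "c")),
                          k = 3, seed = 2)
  typ <- select_typical_cluster(model)
  rev <- detect_reversed_clusters(model, typ)
  mirror_cluster <- unique(model$assignments[sprintf("b%03d", 1:3)])
  same_cluster <- setdiff(1:3, c(typ, mirror_cluster))
  expect_true(mirror_cluster %in% rev)
  expect_false(any(same_cluster %in% rev))
})

test_that("subset construction counts, flips and never duplicates", {
  set.seed(68)
  base <- template_cycle()
  normal <- noisy_cycles(base, 10, sd = 1.5, prefix = "n")
  mirrored <- noisy_cycles(base, 4, sd = 1.5, prefix = "m", swap = TRUE)
  cyc <- c(normal, mirrored)
  model <- cluster_cycles(cyc, k = 2, seed = 13)
  typ <- select_typical_cluster(model)
  rev <- detect_reversed_clusters(model, typ)
  subs <- build_subsets(model, cyc, typ, rev)
  expect_length(subs$subset1$kept_trials, 10L)
  expect_length(subs$subset2$kept_trials, 14L)
  expect_setequal(subs$subset2$flipped_trials, sprintf("m%03d", 1:4))
  expect_false(anyDuplicated(subs$subset2$kept_trials) > 0)
  expect_true(all(subs$subset2$flipped_trials %in% subs$subset2$kept_trials))
  # Flip-corrected cycles are close to the unmirrored template.
  flipped_cycles <- subs$subset2$cycles[
    match(subs$subset2$flipped_trials, subs$subset2$kept_trials)]
  for (fc in flipped_cycles) expect_lt(max(abs(fc$angles - base)), 10)

  # No reversed clusters: subset2 equals subset1.
  subs0 <- build_subsets(model, cyc, typ, integer())
  expect_identical(subs0$subset1$kept_trials, subs0$subset2$kept_trials)
  expect_error(build_subsets(model, cyc, typ, typ), "disjoint")
})

test_that("typical-cluster selection favours gait-shaped clusters", {
  set.seed(69)
  flat <- matrix(20, 101, 4)
  gait <- template_cycle()
  cyc <- c(noisy_cycles(flat, 8, sd = 0.5, prefix = "f"),
           noisy_cycles(gait, 6, sd = 0.5, prefix = "g"))
  model <- cluster_cycles(cyc, k = 2, seed = 17)
  typ <- select_typical_cluster(model)
  expect_setequal(names(model$assignments)[model$assignments == typ],
                  sprintf("g%03d", 1:6))
  expect_equal(select_typical_cluster(model, override = 2), 2L)

  single <- cluster_cycles(cyc[1:3], k = 1, seed = 1)
  expect_equal(select_typical_cluster(single), 1L)
})

test_that("majority orientation wins when reversed trials dominate", {
  set.seed(70)
  base <- template_cycle()
  minority <- noisy_cycles(base, 5, sd = 1.5, prefix = "n")
  majority <- noisy_cycles(base, 15, sd = 1.5, prefix = "m", swap = TRUE)
  model <- cluster_cycles(c(minority, majority), k = 3, seed = 19)
  orient <- resolve_orientation(model)
  flagged <- names(model$assignments)[
    model$assignments %in% orient$reversed]
  expect_setequal(flagged, sprintf("n%03d", 1:5))
})
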