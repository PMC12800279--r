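# MLP classifier training, Shapley attribution and window extraction.

fast_mlp <- function(seed = 1) {
  mlp_config(hidden_width = 32, max_iterations = 150, seed = seed)
}

test_that("separable classes are learned and training is deterministic", {
  set.seed(91)
  co <- make_shift_cohort(n_per_class = 25, delta = 8, noise_sd = 2)
  m1 <- train_classifier(co$cycles, co$labels, fast_mlp(seed = 4))
  expect_gte(m1$metrics$accuracy, 0.95)

  m2 <- train_classifier(co$cycles, co$labels, fast_mlp(seed = 4))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$metrics, m2$metrics)

  expect_error(train_classifier(co$cycles, rep("SCI", 50), fast_mlp()),
               "2 classes")
})

test_that("shuffled labels score near chance on the held-out split", {
  set.seed(92)
  co <- make_window_cohort(n_per_class = 30, delta = 15, noise_sd = 2)
  null_labels <- sample(co$labels)
  m <- train_classifier(co$cycles, null_labels, fast_mlp(seed = 8))
  # Held-out size is 14; 99% binomial band around 0.5.
  expect_gte(m$metrics$accuracy, 0.15)
  expect_lte(m$metrics$accuracy, 0.85)
})

test_that("constant models attribute nothing and linear models their loads", {
  set.seed(93)
  B <- matrix(rnorm(20 * 404), 20, 404)
  x <- rnorm(404)

  const <- shap_attribution(function(X) rep(2.5, nrow(X)), B, x,
                            n_samples = 10, seed = 1)
  expect_true(all(const$values == 0))
  expect_equal(const$baseline, 2.5)

  w <- numeric(404); w[c(5, 150, 300)] <- c(2, -1.5, 0.7)
  lin <- shap_attribution(function(X) as.numeric(X %*% w), B, x,
                          n_samples = 1500, seed = 2)
  phi <- as.vector(lin$values)
  closed <- w * (x - colMeans(B))
  expect_lt(max(abs(phi[c(5, 150, 300)] - closed[c(5, 150, 300)])), 0.2)
  expect_lt(max(abs(phi[-c(5, 150, 300)])), 1e-12)
  expect_error(shap_attribution(function(X) rep(1, nrow(X)), B, x,
                                n_samples = 0), "at least 1")
})

test_that("attribution is exactly additive and differences telescope", {
  set.seed(94)
  co <- make_window_cohort(n_per_class = 15, delta = 12)
  model <- train_classifier(co$cycles, co$labels, fast_mlp(seed = 3),
                            holdout_fraction = 0)
  bg <- co$cycles[co$labels == "Healthy"]
  x1 <- co$cycles[[20]]; x2 <- co$cycles[[25]]
  a1 <- shap_attribution(model, bg, x1, n_samples = 64, seed = 7)
  a2 <- shap_attribution(model, bg, x2, n_samples = 64, seed = 7)
  expect_equal(a1$baseline + sum(a1$values), a1$prediction, tolerance = 1e-10)
  expect_equal(a2$baseline + sum(a2$values), a2$prediction, tolerance = 1e-10)
  expect_equal(sum(a1$values) - sum(a2$values), a1$prediction - a2$prediction,
               tolerance = 1e-10)
})

test_that("window extraction localizes spikes and survives empty maps", {
  zero <- structure(list(values = matrix(0, 101, 4,
                                         dimnames = list(NULL, gait_channels())),
                         baseline = 0, prediction = 0, n_samples = 1,
                         seed = NULL),
                    class = "attribution_map")
  expect_equal(nrow(extract_windows(zero)), 0L)

  spike <- zero
  spike$values[51, "LKnee"] <- 1           # cycle position 50
  w <- extract_windows(spike)
  expect_equal(nrow(w), 1L)
  expect_equal(w$channel, "LKnee")
  expect_true(w$start <= 50 && w$end >= 50)
  expect_equal(w$sign, "increases-SCI-probability")

  two <- spike
  two$values[21:26, "RHip"] <- -0.6
  w2 <- extract_windows(two)
  expect_equal(w2$channel[1], "RHip")      # larger total mass ranks first
  expect_equal(w2$sign[1], "decreases-SCI-probability")
  expect_equal(w2$start[w2$channel == "RHip"], 20)
  expect_equal(w2$end[w2$channel == "RHip"], 25)
})

test_that("attribution mass concentrates on the truly differing window", {
  set.seed(95)
  co <- make_window_cohort(n_per_class = 25, channel = "LKnee",
                           window = c(40, 60), delta = 10)
  model <- train_classifier(co$cycles, co$labels, fast_mlp(seed = 5),
                            holdout_fraction = 0)
  bg <- co$cycles[co$labels == "Healthy"]
  attr <- shap_attribution(model, bg, co$cycles[[30]], n_samples = 256,
                           seed = 6)
  w <- extract_windows(attr)
  expect_gt(nrow(w), 0L)
  expect_equal(w$channel[1], "LKnee")
  expect_true(w$start[1] <= 60 && w$end[1] >= 40)
})
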