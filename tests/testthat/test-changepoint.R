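test_that("moving_sum matches brute force and handles edges", {
  expect_equal(moving_sum(rep(3, 10), 4), c(rep(NA, 3), rep(12, 7)))
  x <- rnorm(20)
  expect_equal(moving_sum(x, 1), x)  # k = 1 identity
  set.seed(3)
  y <- rnorm(200)
  expect_equal(moving_sum(y, 7), brute_moving_sum(y, 7), tolerance = 1e-9)
  expect_error(moving_sum(rnorm(5), 6), "shorter")
})

test_that("mosum_statistic is the lagged window-sum difference", {
  expect_true(all(mosum_statistic(rep(2, 30), 5, 5) == 0, na.rm = TRUE))
  set.seed(4)
  y <- rnorm(150)
  expect_equal(mosum_statistic(y, 6, 4), brute_mosum(y, 6, 4), tolerance = 1e-9)
  # unit step of height h: peak |R| = k*h when k = G
  h <- 2.5
  step <- c(rep(0, 40), rep(h, 40))
  R <- mosum_statistic(step, 7, 7)
  expect_equal(max(abs(R), na.rm = TRUE), 7 * h)
  expect_error(mosum_statistic(rnorm(9), 5, 5), "shorter")
})

test_that("the statistic is translation-invariant and scale-linear", {
  set.seed(5)
  x <- rnorm(120)
  R <- mosum_statistic(x, 5, 5)
  expect_equal(mosum_statistic(x + 17.3, 5, 5), R, tolerance = 1e-9)
  expect_equal(mosum_statistic(3 * x, 5, 5), 3 * R, tolerance = 1e-9)
})

test_that("detection returns nothing on a constant series", {
  res <- detect_change_points(rep(4.2, 80))
  expect_length(res$change_points, 0)
})

test_that("a single step is localized within one bandwidth", {
  set.seed(6)
  t0 <- 60
  x <- c(rep(5, t0 - 1), rep(1, 60)) + rnorm(119, 0, 0.05)
  res <- detect_change_points(x)
  expect_length(res$change_points, 1)
  expect_lte(abs(res$change_points - t0), res$config$G)
  # the selected peak clears the threshold
  expect_true(all(abs(res$statistic[res$peaks + 1L]) >= res$threshold))
})

test_that("noise-free piecewise-constant series are recovered exactly", {
  levels <- c(2, 6, 1.5, 5)
  lens <- c(40, 35, 45, 40)
  x <- rep(levels, lens)
  jumps <- cumsum(lens)[-4] + 1L
  res <- detect_change_points(x)
  expect_length(res$change_points, length(jumps))
  expect_true(all(abs(res$change_points - jumps) <= res$config$G))
})

test_that("raw-mode detection works for piecewise-constant input", {
  x <- c(rep(0, 50), rep(3, 50))
  res <- detect_change_points(x, mosum_config(detrend = "none",
                                              threshold_mode = "absolute",
                                              threshold_value = 5))
  expect_equal(res$change_points, 51L)
})

test_that("configuration is validated", {
  expect_error(mosum_config(threshold_value = 0), "positive")
  expect_error(mosum_config(k = 0), ">= 1")
  expect_error(detect_change_points(rnorm(50), "not a config"), "mosum_config")
})

test_that("fixture cutting events are recovered", {
  fx <- std_fixture()
  res <- detect_change_points(fx$series$lai)
  truth <- fx$change_points$points
  G <- res$config$G
  hits <- vapply(truth, function(p) any(abs(res$change_points - p) <= G),
                 logical(1))
  false_pos <- vapply(res$change_points,
                      function(d) all(abs(truth - d) > G), logical(1))
  expect_gte(sum(hits), 6)
  expect_lte(sum(false_pos), 1)
})
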