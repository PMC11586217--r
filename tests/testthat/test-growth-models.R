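test_that("compute_rlai divides by the (default or given) maximum", {
  expect_equal(compute_rlai(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(compute_rlai(3, lai_max = 6), 0.5)
  expect_equal(max(compute_rlai(runif(20, 0.1, 5))), 1)
  expect_error(compute_rlai(numeric(0)), "non-empty")
  expect_error(compute_rlai(c(0, 0, 0)), "positive")
  expect_error(compute_rlai(c(1, 2), lai_max = -1), "positive")
})

test_that("rlai round-trips through the scale factor", {
  set.seed(11)
  lai <- runif(50, 0, 6.5)
  lm_ <- max(lai)
  expect_equal(compute_rlai(lai) * lm_, lai)
  expect_equal(compute_rlai(lai, 4.2) * 4.2, lai)
})

test_that("logistic evaluation matches independent scalar computation", {
  p <- logistic_params(2.4249, -0.1699, 0.0003)
  # frozen from 1/(1 + exp(a1 + b1*x + c1*x^2)) evaluated by hand
  expect_equal(eval_logistic(p, 12), 0.3942935, tolerance = 1e-6)
  expect_equal(eval_logistic(p, 30), 0.9169873, tolerance = 1e-6)
  # exponent-zero symmetry
  expect_equal(eval_logistic(logistic_params(3, -0.15), 20), 0.5)
  # bounded in (0, 1) even at extreme inputs (no overflow)
  v <- eval_logistic(p, c(-1e6, -50, 0, 50, 1e6))
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(is.finite(v)))
})

test_that("richards conventions behave as declared", {
  # standard convention: increasing, saturates at a2
  p <- richards_params(0.97, 5, 0.2, 2)
  expect_equal(eval_richards(p, 1e6), 0.97)
  expect_true(all(diff(eval_richards(p, 0:80)) > 0))
  # b2 - c2*x = 0 midpoint identity for d = 1
  expect_equal(eval_richards(richards_params(1, 5, 0.2, 1), 25), 0.5)
  # printed convention as written: 1 * (1 + e^0)^1 = 2 at x = 0
  expect_equal(eval_richards(richards_params(1, 0, 0.2, 1), 0, "printed"), 2)
  expect_error(richards_params(1, 0, 0.2, 0), "non-zero")
})

test_that("gompertz evaluation matches asymptote and origin identities", {
  p <- gompertz_params(0.9971, 6.8693, 0.1137)
  expect_equal(eval_gompertz(p, 1e6), 0.9971)
  expect_equal(eval_gompertz(p, 0), 0.8899373, tolerance = 1e-6)  # a3*e^(-c3)
  expect_equal(eval_gompertz(gompertz_params(1, 0.2, 0), c(0, 5, 50)), rep(1, 3))
  # monotone increasing, bounded by a3, for positive rates
  v <- eval_gompertz(gompertz_params(1, 0.15, 12), 0:60)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 1))
})

test_that("fitting recovers generating parameters from clean data", {
  x <- 1:70
  truth <- c(2.4249, -0.1699, 0.0003)
  y <- eval_logistic(logistic_params(truth[1], truth[2], truth[3]), x)
  f <- fit_growth(x, y, "logistic")
  expect_lt(max(abs(unlist(f$params) - truth) / abs(truth)), 1e-4)
  expect_lt(f$rss, 1e-8)
  expect_gte(f$r2, 0.9999)

  yg <- eval_gompertz(gompertz_params(1, 0.15, 12), 1:60)
  fg <- fit_growth(1:60, yg, "gompertz")
  expect_lt(max(abs(unlist(fg$params) - c(1, 0.15, 12)) / c(1, 0.15, 12)), 1e-4)

  yr <- eval_richards(richards_params(1, 5, 0.2, 2), 1:70)
  fr <- fit_growth(1:70, yr, "richards")
  expect_lt(fr$rss, 1e-8)
})

test_that("fitting is robust to observation noise", {
  set.seed(7)
  y <- eval_gompertz(gompertz_params(1, 0.15, 12), 1:60) + rnorm(60, 0, 0.03)
  f <- fit_growth(1:60, y, "gompertz")
  expect_gte(f$r2, 0.95)
})

test_that("fitting rejects under-determined input", {
  expect_error(fit_growth(c(1, 2), c(0.1, 0.2), "logistic"), "under-determined")
  expect_error(fit_growth(rep(5, 10), runif(10), "logistic"), "identical")
  expect_error(fit_growth(1:3, c(0.1, 0.2, 0.3), "richards"), "under-determined")
})

test_that("analytic growth rates match a central-difference oracle", {
  cases <- list(
    logistic_params(2.4249, -0.1699, 0.0003),
    logistic_params(3, -0.15),
    richards_params(0.97, 5, 0.2, 2),
    gompertz_params(1, 0.15, 12))
  for (p in cases) {
    f <- function(z) eval_growth(p, z)
    for (x in c(2, 10.5, 20, 33, 55)) {
      expect_lt(abs(growth_rate(p, x) - num_deriv(f, x)), 1e-6)
    }
  }
})

test_that("fastest growth day matches closed forms", {
  # symmetric logistic: argmax at -a1/b1
  expect_equal(fastest_growth_day(logistic_params(3, -0.15), c(0, 60)), 20,
               tolerance = 1e-4)
  # gompertz inflection at ln(c3)/b3
  expect_equal(fastest_growth_day(gompertz_params(1, 0.15, 12), c(0, 60)),
               log(12) / 0.15, tolerance = 1e-4)
  # gompertz inflection rate identity: a3*b3/e
  p <- gompertz_params(1, 0.15, 12)
  expect_equal(growth_rate(p, log(12) / 0.15), 0.15 / exp(1), tolerance = 1e-10)
  # monotone-decreasing rate: boundary argmax
  expect_equal(fastest_growth_day(gompertz_params(1, 0.2, 0.5), c(5, 40)), 5)
})

test_that("daily augmentation scales the fitted curve", {
  p <- logistic_params(2.4249, -0.1699, 0.0003)
  f <- fit_growth(1:70, eval_logistic(p, 1:70), "logistic")
  out <- augment_daily(f, 3.0, 1:70)
  expect_length(out, 70)
  expect_equal(out[30], 2.7509618, tolerance = 1e-5)
  expect_equal(augment_daily(f, 6.0, 1:70), 2 * out)
  expect_true(all(out >= 0))
  expect_error(augment_daily(f, 3.0, integer(0)), "non-empty")
  expect_error(augment_daily(f, -1, 1:5), "positive")
})

test_that("growth-rate table averages slopes across models", {
  fits <- list(logistic = logistic_params(3, -0.15),
               gompertz = gompertz_params(1, 0.15, 12))
  tab <- growth_rate_table(fits)
  expect_equal(tab$day, c(15, 20, 25, 30, 35, 40))
  expect_equal(tab$mean_slope, (tab$logistic + tab$gompertz) / 2)
})
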