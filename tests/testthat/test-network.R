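test_that("min-max scaling maps training data into [0,1] and inverts", {
  sc <- fit_scaler(matrix(c(10, 20, 30), ncol = 1))
  expect_equal(drop(apply_scaler(matrix(c(10, 20, 30)), sc)), c(0, 0.5, 1))
  expect_warning(fit_scaler(matrix(7, 3, 1)), "constant")
  sc2 <- suppressWarnings(fit_scaler(matrix(7, 3, 1)))
  expect_equal(drop(apply_scaler(matrix(7, 3, 1), sc2)), c(0, 0, 0))
  expect_equal(drop(invert_scaler(apply_scaler(matrix(7, 3, 1), sc2), sc2)),
               c(7, 7, 7))
  set.seed(51)
  X <- matrix(rnorm(60, 10, 4), 20, 3)
  sc3 <- fit_scaler(X)
  expect_lt(max(abs(invert_scaler(apply_scaler(X, sc3), sc3) - X)), 1e-12)
  expect_true(all(apply_scaler(X, sc3) >= 0 & apply_scaler(X, sc3) <= 1))
})

test_that("analytic gradients match finite differences for every variant", {
  loss_fn <- function(params, variant, Xs, x_dec, y) {
    fw <- laicast:::.model_forward(params, variant, Xs, x_dec)
    mean((fw$yhat - y)^2)
  }
  set.seed(1)
  B <- 3; s <- 4; d <- 2; m <- 3
  for (variant in c("lstm", "bilstm", "tmead")) {
    params <- laicast:::.init_model_params(variant, d, m)
    Xs <- lapply(1:s, function(t) matrix(rnorm(B * d), B, d))
    x_dec <- if (variant == "tmead") matrix(rnorm(B * d), B, d) else NULL
    y <- matrix(rnorm(B), B, 1)
    fw <- laicast:::.model_forward(params, variant, Xs, x_dec)
    g <- laicast:::.model_backward(params, fw, y)
    eps <- 1e-6
    worst <- 0
    perturb <- function(tree, path, val) {
      if (length(path) == 1L) tree[[path]] <- val
      else tree[[path[1]]][[path[2]]] <- val
      tree
    }
    fetch <- function(tree, path) {
      if (length(path) == 1L) tree[[path]] else tree[[path[1]]][[path[2]]]
    }
    paths <- list()
    for (nm in names(params)) {
      if (is.list(params[[nm]]))
        for (sub in names(params[[nm]])) paths <- c(paths, list(c(nm, sub)))
      else paths <- c(paths, list(nm))
    }
    for (path in paths) {
      W <- fetch(params, path)
      # spot-check a handful of coordinates per tensor
      idx <- unique(round(seq(1, length(W), length.out = min(6, length(W)))))
      for (i in idx) {
        Wp <- W; Wp[i] <- W[i] + eps
        Wm <- W; Wm[i] <- W[i] - eps
        num <- (loss_fn(perturb(params, path, Wp), variant, Xs, x_dec, y) -
                loss_fn(perturb(params, path, Wm), variant, Xs, x_dec, y)) / (2 * eps)
        worst <- max(worst, abs(num - fetch(g, path)[i]))
      }
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("encoder direction symmetry: reversing input swaps the passes", {
  set.seed(52)
  d <- 3; m <- 4; s <- 5
  p <- laicast:::lstm_init(d, m)
  Xs <- lapply(1:s, function(t) matrix(rnorm(2 * d), 2, d))
  fwd <- laicast:::lstm_seq_forward(Xs, p, reverse = FALSE)
  bwd_rev <- laicast:::lstm_seq_forward(rev(Xs), p, reverse = TRUE)
  for (t in 1:s) {
    expect_equal(fwd$H[[t]], bwd_rev$H[[s - t + 1]], tolerance = 1e-12)
  }
})

test_that("attention weights form a probability vector and average outputs", {
  set.seed(53)
  # all scores equal -> uniform weights, context = mean of outputs
  m <- 3
  eh <- matrix(1, 4, m)
  enc <- cbind(eh, eh)  # identical rows -> equal scores
  at <- attend(enc)
  expect_equal(at$weights, rep(0.25, 4))
  expect_equal(at$context, colMeans(enc))
  # single step -> weight 1
  one <- matrix(rnorm(2 * m), 1)
  at1 <- attend(one)
  expect_equal(at1$weights, 1)
  expect_equal(at1$context, drop(one))
  # random case vs an independent softmax + weighted sum
  enc2 <- matrix(rnorm(6 * 2 * m), 6)
  at2 <- attend(enc2)
  sc <- rowSums(enc2[, 1:m] * enc2[, m + 1:m])
  w <- exp(sc - max(sc)); w <- w / sum(w)
  expect_equal(at2$weights, w, tolerance = 1e-10)
  expect_equal(at2$context, drop(t(w) %*% enc2), tolerance = 1e-10)
  expect_true(all(at2$weights >= 0))
  expect_equal(sum(at2$weights), 1, tolerance = 1e-6)
})

test_that("encode produces per-step outputs of width 2m", {
  fx <- small_fixture()
  cfg <- network_config(variant = "tmead", hidden = 5, max_epochs = 0, seed = 2)
  mdl <- train_lai_model(fx$series, fx$change_points, cfg)
  win <- matrix(runif(6 * 14), 14, 6)
  enc <- encode(mdl, win)
  expect_equal(dim(enc), c(14L, 10L))
  enc1 <- encode(mdl, win[1, , drop = FALSE])
  expect_equal(dim(enc1), c(1L, 10L))
  # context lies in the convex hull of per-step outputs (within its bbox)
  at <- attend(enc)
  expect_true(all(at$context <= apply(enc, 2, max) + 1e-12))
  expect_true(all(at$context >= apply(enc, 2, min) - 1e-12))
  # decode produces one finite LAI value
  pred <- decode_and_project(mdl, at$context, win[14, ])
  expect_length(pred, 1)
  expect_true(is.finite(pred))
})

test_that("training honours epoch budget, filters and seeds", {
  fx <- small_fixture()
  cfg0 <- network_config(variant = "tmead", max_epochs = 0, seed = 3)
  m0 <- train_lai_model(fx$series, fx$change_points, cfg0)
  expect_false(m0$trained)
  expect_equal(nrow(m0$history), 0L)

  cfg <- network_config(variant = "tmead", max_epochs = 3, seed = 3)
  m1 <- train_lai_model(fx$series, fx$change_points, cfg)
  expect_true(m1$trained)
  expect_equal(nrow(m1$history), 3L)
  expect_true(all(is.finite(m1$history$train_loss)))
  m2 <- train_lai_model(fx$series, fx$change_points, cfg)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  fc1 <- predict_series(m1, fx$series)
  fc2 <- predict_series(m2, fx$series)
  expect_identical(fc1$predicted, fc2$predicted)
})

test_that("prediction output is aligned and validated", {
  fx <- small_fixture()
  cfg <- network_config(variant = "lstm", max_epochs = 2, seed = 4)
  mdl <- train_lai_model(fx$series, fx$change_points, cfg)
  fc <- predict_series(mdl, fx$series)
  expect_equal(length(fc$observed), length(fc$predicted))
  expect_equal(fc$observed, fx$series$lai[fc$index])
  # default windows stay inside one regrowth segment
  cps <- fx$change_points$points
  for (ti in fc$index) {
    expect_false(any(cps > ti - mdl$window & cps <= ti))
  }
  expect_error(predict_series(mdl, fx$series, starts = 10000), "range")
  expect_error(predict_series(mdl, fx$series[1, ]), "too short")
})

test_that("models survive a JSON round trip", {
  fx <- small_fixture()
  cfg <- network_config(variant = "tmead", max_epochs = 2, seed = 5)
  mdl <- train_lai_model(fx$series, fx$change_points, cfg)
  tmp <- tempfile(fileext = ".json")
  save_lai_model(mdl, tmp)
  back <- load_lai_model(tmp)
  fc1 <- predict_series(mdl, fx$series)
  fc2 <- predict_series(back, fx$series, starts = fc1$index - mdl$window)
  expect_equal(fc2$predicted, fc1$predicted, tolerance = 1e-12)
})
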