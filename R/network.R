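#' Network configuration
#'
#' Settings of the recurrent LAI forecaster and its training loop. Defaults
#' follow the reference recipe: 12 hidden units per direction, Adam at
#' learning rate 0.6e-3, minibatches of 32 windows, at most 300 epochs with
#' early stopping.
#'
#' @param variant One of `"lstm"`, `"bilstm"`, `"mlstm"`, `"mbilstm"`,
#'   `"tmead"`. The `m*` variants train only on change-point-free windows;
#'   `"tmead"` additionally uses the attention encoder-decoder architecture.
#' @param hidden Hidden units per direction (default 12).
#' @param window Input window length `s`; `NULL` (default) resolves to
#'   `min(14, s_max)` with `s_max` from [max_batch_size()].
#' @param horizon Forecast steps ahead (only 1 supported).
#' @param lr Adam learning rate.
#' @param minibatch Windows per minibatch.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); best-validation weights are restored.
#' @param seed RNG seed controlling parameter initialization and window
#'   sampling.
#' @param relu_in_cell Reserved knob; the recurrent cells keep their
#'   standard tanh/sigmoid nonlinearities and ReLU sits on the fully
#'   connected head.
#' @return A `network_config` list.
#' @export
network_config <- function(variant = c("tmead", "lstm", "bilstm", "mlstm", "mbilstm"),
                           hidden = 12L, window = NULL, horizon = 1L,
                           lr = 0.6e-3, minibatch = 32L, max_epochs = 300L,
                           patience = 20L, seed = 42L, relu_in_cell = FALSE) {
  variant <- match.arg(variant)
  hidden <- as.integer(hidden)
  if (hidden < 1L) stop("`hidden` must be >= 1", call. = FALSE)
  if (!is.null(window) && window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (as.integer(horizon) != 1L)
    stop("only horizon = 1 is supported", call. = FALSE)
  if (lr <= 0) stop("`lr` must be positive", call. = FALSE)
  structure(list(variant = variant, hidden = hidden, window = window,
                 horizon = 1L, lr = lr, minibatch = as.integer(minibatch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 relu_in_cell = isTRUE(relu_in_cell)),
            class = "network_config")
}

.variant_filters <- c(lstm = FALSE, bilstm = FALSE, mlstm = TRUE,
                      mbilstm = TRUE, tmead = TRUE)
.variant_bidir <- c(lstm = FALSE, bilstm = TRUE, mlstm = FALSE,
                    mbilstm = TRUE, tmead = TRUE)

## ---- min-max feature scaling --------------------------------------------

#' Min-max feature scaler
#'
#' Per-feature affine map to `[0, 1]` fitted on the training split. Constant
#' features are mapped to 0 (with a warning at fit time) and inverted back to
#' their constant value.
#'
#' @param X Numeric matrix or data.frame of features (columns = features).
#' @return A `feature_scaler` with per-feature `min` and `max`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty input to `fit_scaler`", call. = FALSE)
  mn <- apply(X, 2L, min)
  mx <- apply(X, 2L, max)
  if (any(mx <= mn))
    warning("constant feature(s) mapped to 0: ",
            paste(colnames(X)[mx <= mn], collapse = ", "), call. = FALSE)
  structure(list(min = mn, max = mx), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_scaler <- function(X, scaler) {
  X <- as.matrix(X)
  rng <- scaler$max - scaler$min
  rng[rng <= 0] <- Inf   # constant feature -> 0
  sweep(sweep(X, 2L, scaler$min, "-"), 2L, rng, "/")
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(X, scaler) {
  X <- as.matrix(X)
  rng <- scaler$max - scaler$min
  rng[rng <= 0] <- 0
  sweep(sweep(X, 2L, rng, "*"), 2L, scaler$min, "+")
}

## ---- model ----------------------------------------------------------------

.init_model_params <- function(variant, d, m) {
  r <- 1 / sqrt(m)
  p <- list(enc_f = lstm_init(d, m))
  if (.variant_bidir[[variant]]) p$enc_b <- lstm_init(d, m)
  if (variant == "tmead") {
    p$dec_f <- lstm_init(d + 2L * m, m)
    p$dec_b <- lstm_init(d + 2L * m, m)
  }
  head_in <- if (.variant_bidir[[variant]]) 2L * m else m
  p$W1 <- .init_mat(head_in, m, r)
  p$b1 <- matrix(0, 1, m)
  p$W2 <- .init_mat(m, 1L, r)
  p$b2 <- matrix(0, 1, 1)
  p
}

# Forward pass on a minibatch. Xs: list of s feature matrices (B x d),
# x_dec: B x d target-step covariates (tmead only). Returns yhat and cache.
.model_forward <- function(params, variant, Xs, x_dec = NULL) {
  B <- nrow(Xs[[1L]])
  ca <- list()
  if (variant == "tmead") {
    ef <- lstm_seq_forward(Xs, params$enc_f, reverse = FALSE)
    eb <- lstm_seq_forward(Xs, params$enc_b, reverse = TRUE)
    s <- length(Xs); m <- ef$M
    score <- matrix(0, B, s)
    for (t in seq_len(s)) score[, t] <- rowSums(ef$H[[t]] * eb$H[[t]])
    A <- .softmax_rows(score)
    context <- matrix(0, B, 2L * m)
    for (t in seq_len(s))
      context <- context + A[, t] * cbind(ef$H[[t]], eb$H[[t]])
    u <- cbind(x_dec, context)
    df <- lstm_seq_forward(list(u), params$dec_f, reverse = FALSE)
    db <- lstm_seq_forward(list(u), params$dec_b, reverse = TRUE)
    feat <- cbind(df$h_last, db$h_last)
    ca <- list(ef = ef, eb = eb, A = A, context = context, u = u,
               df = df, db = db)
  } else if (.variant_bidir[[variant]]) {
    ef <- lstm_seq_forward(Xs, params$enc_f, reverse = FALSE)
    eb <- lstm_seq_forward(Xs, params$enc_b, reverse = TRUE)
    feat <- cbind(ef$h_last, eb$h_last)
    ca <- list(ef = ef, eb = eb)
  } else {
    ef <- lstm_seq_forward(Xs, params$enc_f, reverse = FALSE)
    feat <- ef$h_last
    ca <- list(ef = ef)
  }
  pre <- feat %*% params$W1 + matrix(params$b1, B, ncol(params$W1), byrow = TRUE)
  hh <- .relu(pre)
  yhat <- hh %*% params$W2 + matrix(params$b2, B, 1L)
  c(ca, list(feat = feat, hh = hh, yhat = yhat, variant = variant, s = length(Xs)))
}

# Backward pass for mean-squared-error loss; returns the gradient tree.
.model_backward <- function(params, cache, y) {
  B <- nrow(cache$yhat)
  variant <- cache$variant
  dyhat <- 2 * (cache$yhat - y) / B
  g <- list()
  g$W2 <- crossprod(cache$hh, dyhat)
  g$b2 <- matrix(sum(dyhat), 1, 1)
  dhh <- (dyhat %*% t(params$W2)) * (cache$hh > 0)
  g$W1 <- crossprod(cache$feat, dhh)
  g$b1 <- matrix(colSums(dhh), 1)
  dfeat <- dhh %*% t(params$W1)
  m <- nrow(params$W1) / (if (.variant_bidir[[variant]]) 2L else 1L)

  if (variant == "tmead") {
    s <- cache$s
    ddf <- dfeat[, seq_len(m), drop = FALSE]
    ddb <- dfeat[, m + seq_len(m), drop = FALSE]
    bdf <- lstm_seq_backward(list(ddf), cache$df, params$dec_f)
    bdb <- lstm_seq_backward(list(ddb), cache$db, params$dec_b)
    g$dec_f <- list(Wx = bdf$dWx, Wh = bdf$dWh, b = bdf$db)
    g$dec_b <- list(Wx = bdb$dWx, Wh = bdb$dWh, b = bdb$db)
    du <- bdf$dX[[1L]] + bdb$dX[[1L]]
    d <- ncol(cache$u) - 2L * m
    dcontext <- du[, d + seq_len(2L * m), drop = FALSE]

    A <- cache$A
    ef <- cache$ef; eb <- cache$eb
    dHf <- vector("list", s); dHb <- vector("list", s)
    dA <- matrix(0, B, s)
    for (t in seq_len(s)) {
      enc_t <- cbind(ef$H[[t]], eb$H[[t]])
      dA[, t] <- rowSums(dcontext * enc_t)
      denc_t <- A[, t] * dcontext
      dHf[[t]] <- denc_t[, seq_len(m), drop = FALSE]
      dHb[[t]] <- denc_t[, m + seq_len(m), drop = FALSE]
    }
    dscore <- A * (dA - rowSums(A * dA))
    for (t in seq_len(s)) {
      dHf[[t]] <- dHf[[t]] + dscore[, t] * eb$H[[t]]
      dHb[[t]] <- dHb[[t]] + dscore[, t] * ef$H[[t]]
    }
    bef <- lstm_seq_backward(dHf, ef, params$enc_f)
    beb <- lstm_seq_backward(dHb, eb, params$enc_b)
    g$enc_f <- list(Wx = bef$dWx, Wh = bef$dWh, b = bef$db)
    g$enc_b <- list(Wx = beb$dWx, Wh = beb$dWh, b = beb$db)
  } else if (.variant_bidir[[variant]]) {
    s <- cache$s
    dHf <- vector("list", s); dHb <- vector("list", s)
    dHf[[s]] <- dfeat[, seq_len(m), drop = FALSE]
    dHb[[1L]] <- dfeat[, m + seq_len(m), drop = FALSE]
    bef <- lstm_seq_backward(dHf, cache$ef, params$enc_f)
    beb <- lstm_seq_backward(dHb, cache$eb, params$enc_b)
    g$enc_f <- list(Wx = bef$dWx, Wh = bef$dWh, b = bef$db)
    g$enc_b <- list(Wx = beb$dWx, Wh = beb$dWh, b = beb$db)
  } else {
    s <- cache$s
    dHf <- vector("list", s)
    dHf[[s]] <- dfeat
    bef <- lstm_seq_backward(dHf, cache$ef, params$enc_f)
    g$enc_f <- list(Wx = bef$dWx, Wh = bef$dWh, b = bef$db)
  }
  g[names(params)]
}

## ---- public architecture surface -----------------------------------------

#' Encode a window with the bidirectional encoder
#'
#' Runs the forward and backward encoder passes over one scaled feature
#' window and concatenates the per-step states.
#'
#' @param model A trained (or initialized) `lai_model`.
#' @param window An `s x d` matrix of scaled features (one row per step).
#' @return An `s x 2m` matrix of encoder outputs `[e_h,i ; e_b,i]`.
#' @export
encode <- function(model, window) {
  stopifnot(inherits(model, "lai_model"))
  if (!.variant_bidir[[model$variant]])
    stop("encode() requires a bidirectional variant", call. = FALSE)
  window <- as.matrix(window)
  if (ncol(window) != model$input_dim)
    stop("window has wrong feature dimension", call. = FALSE)
  Xs <- lapply(seq_len(nrow(window)), function(t) window[t, , drop = FALSE])
  ef <- lstm_seq_forward(Xs, model$params$enc_f, reverse = FALSE)
  eb <- lstm_seq_forward(Xs, model$params$enc_b, reverse = TRUE)
  out <- do.call(rbind, lapply(seq_along(Xs),
                               function(t) cbind(ef$H[[t]], eb$H[[t]])))
  out
}

#' Attention over encoder outputs
#'
#' Scores each step by the inner product of its forward and backward states,
#' normalizes the scores with a softmax, and returns the weighted average of
#' the encoder outputs as the context vector.
#'
#' @param enc_outputs An `s x 2m` matrix of encoder outputs (forward states
#'   in the first half of the columns).
#' @return A list: `weights` (length `s`, nonnegative, summing to 1) and
#'   `context` (length `2m`).
#' @export
attend <- function(enc_outputs) {
  enc_outputs <- as.matrix(enc_outputs)
  if (!nrow(enc_outputs)) stop("empty encoder outputs", call. = FALSE)
  m <- ncol(enc_outputs) / 2L
  score <- rowSums(enc_outputs[, seq_len(m), drop = FALSE] *
                   enc_outputs[, m + seq_len(m), drop = FALSE])
  w <- drop(.softmax_rows(matrix(score, 1L)))
  list(weights = w, context = drop(w %*% enc_outputs))
}

#' Decode a context vector into a LAI forecast
#'
#' The bidirectional decoder consumes the target-step covariates concatenated
#' with the attention context, and the fully connected head (ReLU then
#' linear) maps the decoder states to the prediction, inverse-scaled to LAI
#' units.
#'
#' @param model A `lai_model` (variant `"tmead"`).
#' @param context Length-`2m` context vector from [attend()].
#' @param x_dec Length-`d` scaled covariate vector for the target step.
#' @return Predicted LAI (length-`horizon` numeric, original scale).
#' @export
decode_and_project <- function(model, context, x_dec) {
  stopifnot(inherits(model, "lai_model"))
  if (model$variant != "tmead")
    stop("decode_and_project() requires the tmead variant", call. = FALSE)
  if (length(x_dec) != model$input_dim)
    stop("`x_dec` has wrong feature dimension", call. = FALSE)
  p <- model$params
  u <- matrix(c(x_dec, context), 1L)
  df <- lstm_seq_forward(list(u), p$dec_f, reverse = FALSE)
  db <- lstm_seq_forward(list(u), p$dec_b, reverse = TRUE)
  feat <- cbind(df$h_last, db$h_last)
  hh <- .relu(feat %*% p$W1 + p$b1)
  yhat <- hh %*% p$W2 + p$b2
  drop(invert_scaler(yhat, model$target_scaler))
}

## ---- data plumbing --------------------------------------------------------

.feature_names <- c("gdd", "growth_days", "sm10", "sm20", "sm30", "lai")

# Encoder features: covariates + LAI at each step. Decoder features at the
# target step: covariates at the target day plus the last observed LAI
# (all known at one-step-ahead forecast time).
.build_features <- function(series) {
  Fe <- as.matrix(series[.feature_names])
  Fd <- Fe
  Fd[, "lai"] <- c(Fe[1, "lai"], Fe[-nrow(Fe), "lai"])
  list(Fe = Fe, Fd = Fd, y = series$lai)
}

.chrono_splits <- function(n) {
  test_len <- floor(0.2 * n)
  trainval_end <- n - test_len
  val_len <- floor(0.2 * trainval_end)
  list(train_end = trainval_end - val_len,
       val_start = trainval_end - val_len + 1L, val_end = trainval_end,
       test_start = trainval_end + 1L, n = n)
}

# Minibatch tensors for a set of window starts. The decoder consumes the
# final window step's covariates (nothing from the forecast target's day).
.gather_batch <- function(starts, s, Fe_s, Fd_s, y_s) {
  Xs <- lapply(seq_len(s), function(t) Fe_s[starts + t - 1L, , drop = FALSE])
  ti <- starts + s
  list(Xs = Xs, x_dec = Fe_s[starts + s - 1L, , drop = FALSE],
       y = matrix(y_s[ti], ncol = 1L), targets = ti)
}

.batch_predict <- function(params, variant, starts, s, Fe_s, Fd_s, y_s) {
  b <- .gather_batch(starts, s, Fe_s, Fd_s, y_s)
  fw <- .model_forward(params, variant,
                       b$Xs, if (variant == "tmead") b$x_dec else NULL)
  list(yhat = fw$yhat, y = b$y, targets = b$targets)
}

## ---- training -------------------------------------------------------------

#' Train a LAI forecaster
#'
#' Chronological splits (last 20% test; of the remainder, last 20%
#' validation), min-max scaling fitted on the training region, minibatch
#' Adam on mean squared error, early stopping on validation loss with
#' best-weight restoration. Variants `mlstm`, `mbilstm` and `tmead` draw
#' training windows only from change-point-free starts (window plus
#' forecast target); `lstm` and `bilstm` sample unrestricted windows.
#'
#' @param series A `lai_series` data.frame (e.g. from [simulate_dataset()]).
#' @param cps Change points ([change_point_set()]); `NULL` runs
#'   [detect_change_points()] on the LAI column with default settings.
#' @param config A [network_config()].
#' @return A `lai_model`: `params`, `variant`, `config`, fitted scalers,
#'   `window` length, split bookkeeping, and per-epoch `history`
#'   (train/validation loss).
#' @export
train_lai_model <- function(series, cps = NULL, config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  variant <- config$variant
  n <- nrow(series)
  if (is.null(cps)) {
    det <- detect_change_points(series$lai)
    cps <- change_point_set(det$change_points, n)
  }
  cps <- .as_cps(cps, n)

  set.seed(config$seed)
  sp <- .chrono_splits(n)
  dat <- .build_features(series)
  scaler <- fit_scaler(dat$Fe[seq_len(sp$train_end), , drop = FALSE])
  target_scaler <- structure(list(min = scaler$min["lai"],
                                  max = scaler$max["lai"]),
                             class = "feature_scaler")
  Fe_s <- apply_scaler(dat$Fe, scaler)
  Fd_s <- apply_scaler(dat$Fd, scaler)
  y_s <- drop(apply_scaler(matrix(dat$y, ncol = 1L), target_scaler))

  s <- config$window %||% min(14L, max_batch_size(cps))
  s <- as.integer(s)
  if (sp$train_end - s < 1L)
    stop("series too short for one training window", call. = FALSE)

  d <- ncol(Fe_s); m <- config$hidden
  params <- .init_model_params(variant, d, m)

  model <- structure(list(
    variant = variant, params = params, config = config, scaler = scaler,
    target_scaler = target_scaler, input_dim = d, window = s,
    feature_names = .feature_names, change_points = cps, splits = sp,
    history = data.frame(epoch = integer(), train_loss = numeric(),
                         val_loss = numeric()),
    trained = FALSE), class = "lai_model")
  if (config$max_epochs < 1L) return(model)

  filtered <- .variant_filters[[variant]]
  train_cps <- cps$points[cps$points <= sp$train_end]
  vs_check <- if (filtered) valid_starts(sp$train_end, s, train_cps, margin = 1L)
              else seq_len(sp$train_end - s)
  if (!length(vs_check))
    stop("no valid window: every training window contains a change point",
         call. = FALSE)

  if (sp$val_end - s < sp$val_start)
    stop("validation split too short for one window", call. = FALSE)
  val_starts <- seq.int(sp$val_start, sp$val_end - s)
  # score validation on the same within-segment task as evaluation:
  # windows (plus target) crossing a cut are unpredictable by design and
  # would reduce the early-stopping signal to noise
  keep <- vapply(val_starts, function(st)
    !any(cps$points >= st & cps$points <= st + s), logical(1))
  if (any(keep)) val_starts <- val_starts[keep]

  opt <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- vector("list", config$max_epochs)
  stall <- 0L

  for (ep in seq_len(config$max_epochs)) {
    batches <- make_training_batches(sp$train_end, s, train_cps,
                                     minibatch_size = config$minibatch,
                                     margin = 1L, filter = filtered)
    ep_loss <- 0
    for (bt in batches) {
      b <- .gather_batch(bt$start, s, Fe_s, Fd_s, y_s)
      fw <- .model_forward(params, variant, b$Xs,
                           if (variant == "tmead") b$x_dec else NULL)
      loss <- mean((fw$yhat - b$y)^2)
      if (!is.finite(loss)) stop("training diverged: non-finite loss",
                                 call. = FALSE)
      ep_loss <- ep_loss + loss
      grads <- .model_backward(params, fw, b$y)
      stp <- adam_step(params, grads, opt, lr = config$lr)
      params <- stp$params
      opt <- stp$state
    }
    ep_loss <- ep_loss / length(batches)

    vp <- .batch_predict(params, variant, val_starts, s, Fe_s, Fd_s, y_s)
    val_loss <- mean((vp$yhat - vp$y)^2)
    if (!is.finite(val_loss)) stop("training diverged: non-finite loss",
                                   call. = FALSE)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss,
                             val_loss = val_loss)
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, params = params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$trained <- TRUE
  model
}

#' @export
print.lai_model <- function(x, ...) {
  cat(sprintf("<lai_model> variant = %s, hidden = %d, window = %d, trained = %s\n",
              x$variant, x$config$hidden, x$window, x$trained))
  if (nrow(x$history)) {
    cat(sprintf("  epochs run = %d, best epoch = %d (val MSE %.5g)\n",
                max(x$history$epoch), x$best_epoch,
                min(x$history$val_loss)))
  }
  invisible(x)
}

## ---- prediction -----------------------------------------------------------

#' One-step-ahead forecasts over the test split
#'
#' Slides the trained model across the test region (or the supplied window
#' starts), producing aligned observed/predicted LAI pairs and their
#' accuracy metrics.
#'
#' @param model A trained `lai_model`.
#' @param series The `lai_series` to forecast on (must carry the covariate
#'   columns the model was trained with).
#' @param starts Optional integer window starts; default all windows fully
#'   inside the test split.
#' @param exclude_changepoints Drop default windows whose span (window plus
#'   forecast target) crosses a known change point (default `TRUE`). Cutting
#'   events are scheduled management interventions, so one-step forecasts are
#'   defined within regrowth segments; set to `FALSE` to score through-cut
#'   windows as well. Explicit `starts` are never filtered.
#' @return A `lai_forecast`: data.frame fields `index`, `date`, `observed`,
#'   `predicted`, plus `metrics` ([metrics_report()]).
#' @export
predict_series <- function(model, series, starts = NULL,
                           exclude_changepoints = TRUE) {
  stopifnot(inherits(model, "lai_model"))
  if (!all(model$feature_names %in% names(series)))
    stop("series lacks required covariate columns", call. = FALSE)
  n <- nrow(series)
  s <- model$window
  if (is.null(starts)) {
    sp <- .chrono_splits(n)
    if (sp$test_start > n - s) stop("test split too short for one window",
                                    call. = FALSE)
    starts <- seq.int(sp$test_start, n - s)
    if (isTRUE(exclude_changepoints) && length(model$change_points$points)) {
      cp <- model$change_points$points
      keep <- vapply(starts, function(st)
        !any(cp >= st & cp <= st + s), logical(1))
      starts <- starts[keep]
    }
  }
  starts <- as.integer(starts)
  if (!length(starts)) stop("no forecast windows requested", call. = FALSE)
  if (any(starts < 1L | starts + s > n))
    stop("window starts out of range", call. = FALSE)

  dat <- .build_features(series)
  Fe_s <- apply_scaler(dat$Fe, model$scaler)
  Fd_s <- apply_scaler(dat$Fd, model$scaler)
  y_s <- drop(apply_scaler(matrix(dat$y, ncol = 1L), model$target_scaler))
  pr <- .batch_predict(model$params, model$variant, starts, s, Fe_s, Fd_s, y_s)
  predicted <- drop(invert_scaler(pr$yhat, model$target_scaler))
  observed <- dat$y[pr$targets]
  structure(list(index = pr$targets, date = series$date[pr$targets],
                 observed = observed, predicted = predicted,
                 metrics = metrics_report(observed, predicted)),
            class = "lai_forecast")
}

#' @export
print.lai_forecast <- function(x, ...) {
  cat(sprintf("<lai_forecast> %d one-step forecasts\n", length(x$index)))
  print(x$metrics)
  invisible(x)
}

## ---- persistence ----------------------------------------------------------

#' Save / load a trained model as JSON
#'
#' Serializes the learned weights together with the configuration, scaler
#' bounds and change points into a single portable JSON file.
#'
#' @param model A `lai_model`.
#' @param path Output / input path.
#' @export
save_lai_model <- function(model, path) {
  stopifnot(inherits(model, "lai_model"))
  obj <- list(variant = model$variant,
              config = unclass(model$config),
              window = model$window,
              input_dim = model$input_dim,
              feature_names = model$feature_names,
              scaler = lapply(unclass(model$scaler), as.numeric),
              scaler_names = names(model$scaler$min),
              target_scaler = lapply(unclass(model$target_scaler), as.numeric),
              change_points = model$change_points$points,
              n = model$change_points$n,
              trained = model$trained,
              params = rapply(model$params, function(x)
                list(dim = dim(x), data = as.numeric(x)),
                how = "list"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_lai_model
#' @export
load_lai_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(x) {
    if (is.list(x) && !is.null(x$dim))
      return(matrix(x$data, x$dim[1], x$dim[2]))
    lapply(x, rebuild)
  }
  cfg <- obj$config
  config <- network_config(variant = cfg$variant, hidden = cfg$hidden,
                           window = obj$window,
                           lr = cfg$lr, minibatch = cfg$minibatch,
                           max_epochs = cfg$max_epochs, patience = cfg$patience,
                           seed = cfg$seed)
  scaler <- structure(list(min = stats::setNames(obj$scaler$min, obj$scaler_names),
                           max = stats::setNames(obj$scaler$max, obj$scaler_names)),
                      class = "feature_scaler")
  tsc <- structure(list(min = obj$target_scaler$min,
                        max = obj$target_scaler$max),
                   class = "feature_scaler")
  structure(list(variant = obj$variant, params = rebuild(obj$params),
                 config = config, scaler = scaler, target_scaler = tsc,
                 input_dim = obj$input_dim, window = obj$window,
                 feature_names = obj$feature_names,
                 change_points = change_point_set(obj$change_points, obj$n),
                 splits = NULL,
                 history = data.frame(), trained = isTRUE(obj$trained)),
            class = "lai_model")
}
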