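#' Relative leaf area index
#'
#' Normalizes a series of LAI observations by a reference maximum so that
#' growth curves from plots with different canopy ceilings become comparable
#' on a common (approximately 0--1) scale.
#'
#' @param lai Numeric vector of LAI values (dimensionless, >= 0).
#' @param lai_max Positive reference maximum. Defaults to `max(lai)`, in which
#'   case the rescaled series attains exactly 1 at its maximum.
#' @return Numeric vector `lai / lai_max`. Values above 1 are permitted when an
#'   external `lai_max` smaller than the observed maximum is supplied.
#' @examples
#' compute_rlai(c(1, 2, 4))        # 0.25 0.50 1.00
#' compute_rlai(3, lai_max = 6)    # 0.5
#' @export
compute_rlai <- function(lai, lai_max = NULL) {
  if (length(lai) == 0L) stop("`lai` must be non-empty", call. = FALSE)
  if (!all(is.finite(lai))) stop("`lai` must be finite", call. = FALSE)
  if (is.null(lai_max)) lai_max <- max(lai)
  if (!is.finite(lai_max) || lai_max <= 0)
    stop("`lai_max` must be a positive scalar (all-zero `lai` has no usable maximum)",
         call. = FALSE)
  lai / lai_max
}

## ---- parameter containers ------------------------------------------------

#' Growth-model parameter sets
#'
#' Constructors for the coefficient containers of the three sigmoidal relative
#' LAI models. `x` below is growth days since cut (or sowing).
#'
#' * Logistic: `RLAI = 1 / (1 + exp(a1 + b1*x + c1*x^2))`. The quadratic term
#'   (`c1 > 0`) lets the curve bend downward late in a cut.
#' * Richards: `RLAI = a2 * (1 + exp(b2 - c2*x))^(-1/d)` in the `"standard"`
#'   (monotone-increasing) convention; the `"printed"` convention uses the
#'   exponent `+1/d`.
#' * Gompertz: `RLAI = a3 * exp(-c3 * exp(-b3*x))`.
#'
#' @param a1,b1,c1 Logistic exponent-polynomial coefficients.
#' @param a2,b2,c2,d Richards asymptote scale, shift, rate and shape (`d != 0`).
#' @param a3,b3,c3 Gompertz asymptote (`a3 > 0`), rate and displacement.
#' @return A classed list of coefficients.
#' @export
logistic_params <- function(a1, b1, c1 = 0) {
  p <- list(a1 = a1, b1 = b1, c1 = c1)
  stopifnot(all(vapply(p, is.finite, logical(1))))
  structure(p, class = c("logistic_params", "growth_params"))
}

#' @rdname logistic_params
#' @export
richards_params <- function(a2, b2, c2, d) {
  p <- list(a2 = a2, b2 = b2, c2 = c2, d = d)
  stopifnot(all(vapply(p, is.finite, logical(1))))
  if (d == 0) stop("Richards shape `d` must be non-zero", call. = FALSE)
  structure(p, class = c("richards_params", "growth_params"))
}

#' @rdname logistic_params
#' @export
gompertz_params <- function(a3, b3, c3) {
  p <- list(a3 = a3, b3 = b3, c3 = c3)
  stopifnot(all(vapply(p, is.finite, logical(1))))
  if (a3 <= 0) stop("Gompertz asymptote `a3` must be positive", call. = FALSE)
  structure(p, class = c("gompertz_params", "growth_params"))
}

.clamp_exp <- function(u) pmin(pmax(u, -700), 700)

## ---- model evaluation ----------------------------------------------------

#' Evaluate the logistic relative-LAI model
#'
#' `RLAI(x) = 1 / (1 + exp(a1 + b1*x + c1*x^2))`. The exponent is clamped so
#' the value saturates to 0 or 1 instead of overflowing.
#'
#' @param params A [logistic_params()] object (or numeric vector `(a1, b1, c1)`).
#' @param x Growth days (numeric vector).
#' @return RLAI values in (0, 1).
#' @export
eval_logistic <- function(params, x) {
  p <- .as_params(params, "logistic")
  u <- .clamp_exp(p$a1 + p$b1 * x + p$c1 * x^2)
  1 / (1 + exp(u))
}

#' Evaluate the Richards relative-LAI model
#'
#' The `"standard"` convention, `a2 * (1 + exp(b2 - c2*x))^(-1/d)`, is the
#' conventional monotone-increasing generalized sigmoid and the fitting
#' default. The `"printed"` convention uses exponent `+1/d`, which for
#' `c2 > 0` decreases with `x`; it is kept selectable for completeness.
#'
#' @param params A [richards_params()] object (or numeric vector `(a2, b2, c2, d)`).
#' @param x Growth days.
#' @param convention `"standard"` or `"printed"` (see Details).
#' @return RLAI values.
#' @export
eval_richards <- function(params, x, convention = c("standard", "printed")) {
  p <- .as_params(params, "richards")
  convention <- match.arg(convention)
  z <- .clamp_exp(p$b2 - p$c2 * x)
  base <- 1 + exp(z)
  pow <- if (convention == "standard") -1 / p$d else 1 / p$d
  out <- p$a2 * base^pow
  if (!all(is.finite(out)))
    stop("non-finite value in Richards evaluation", call. = FALSE)
  out
}

#' Evaluate the Gompertz relative-LAI model
#'
#' `RLAI(x) = a3 * exp(-c3 * exp(-b3*x))`; for `b3, c3 > 0` monotone
#' increasing with asymptote `a3`.
#'
#' @param params A [gompertz_params()] object (or numeric vector `(a3, b3, c3)`).
#' @param x Growth days.
#' @return RLAI values.
#' @export
eval_gompertz <- function(params, x) {
  p <- .as_params(params, "gompertz")
  p$a3 * exp(-p$c3 * exp(.clamp_exp(-p$b3 * x)))
}

#' Evaluate any fitted growth model
#'
#' @param fit A [fit_growth()] result, or a `growth_params` object.
#' @param x Growth days.
#' @param convention Richards convention, used only for Richards parameters.
#' @return RLAI values.
#' @export
eval_growth <- function(fit, x, convention = NULL) {
  if (inherits(fit, "growth_fit")) {
    convention <- convention %||% fit$convention
    params <- fit$params
    kind <- fit$kind
  } else {
    params <- fit
    kind <- .params_kind(fit)
  }
  switch(kind,
    logistic = eval_logistic(params, x),
    richards = eval_richards(params, x, convention %||% "standard"),
    gompertz = eval_gompertz(params, x)
  )
}

.params_kind <- function(params) {
  if (inherits(params, "logistic_params")) return("logistic")
  if (inherits(params, "richards_params")) return("richards")
  if (inherits(params, "gompertz_params")) return("gompertz")
  stop("not a growth_params object", call. = FALSE)
}

.as_params <- function(params, kind) {
  if (inherits(params, paste0(kind, "_params"))) return(params)
  if (inherits(params, "growth_params"))
    stop(sprintf("expected %s parameters, got %s", kind, .params_kind(params)),
         call. = FALSE)
  v <- as.numeric(unlist(params))
  switch(kind,
    logistic = logistic_params(v[1], v[2], if (length(v) >= 3) v[3] else 0),
    richards = richards_params(v[1], v[2], v[3], v[4]),
    gompertz = gompertz_params(v[1], v[2], v[3])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- fitting -------------------------------------------------------------

.growth_npar <- c(logistic = 3L, richards = 4L, gompertz = 3L)

# Deterministic multi-start grids; magnitudes bracket typical per-cut fits
# (midpoints 15-35 days, rates 0.1-0.3 per day).
.growth_starts <- function(kind) {
  switch(kind,
    logistic = list(
      c(a1 = 2,   b1 = -0.10, c1 = 0),
      c(a1 = 3,   b1 = -0.15, c1 = 0),
      c(a1 = 4,   b1 = -0.20, c1 = 0),
      c(a1 = 1.5, b1 = -0.08, c1 = 0),
      c(a1 = 5,   b1 = -0.30, c1 = 0)),
    richards = list(
      c(a2 = 1,    b2 = 1, c2 = 0.10, d = 1),
      c(a2 = 1,    b2 = 2, c2 = 0.15, d = 2),
      c(a2 = 0.95, b2 = 3, c2 = 0.20, d = 1),
      c(a2 = 1,    b2 = 5, c2 = 0.10, d = 0.5),
      c(a2 = 1,    b2 = 1, c2 = 0.05, d = 1)),
    gompertz = list(
      c(a3 = 1,    b3 = 0.10, c3 = 10),
      c(a3 = 1,    b3 = 0.15, c3 = 12),
      c(a3 = 1,    b3 = 0.20, c3 = 8),
      c(a3 = 1.1,  b3 = 0.10, c3 = 5),
      c(a3 = 0.95, b3 = 0.12, c3 = 15)))
}

.growth_bounds <- function(kind) {
  switch(kind,
    logistic = list(lower = rep(-Inf, 3), upper = rep(Inf, 3)),
    # a2 > 0, rate > 0, shape d bounded away from 0
    richards = list(lower = c(1e-8, -50, 1e-6, 0.02), upper = c(20, 50, 5, 50)),
    gompertz = list(lower = c(1e-8, 1e-8, 0), upper = c(Inf, Inf, Inf)))
}

.growth_formula <- function(kind, convention) {
  switch(kind,
    logistic = y ~ 1 / (1 + exp(a1 + b1 * x + c1 * x^2)),
    richards = if (convention == "standard")
      y ~ a2 * (1 + exp(b2 - c2 * x))^(-1 / d)
    else
      y ~ a2 * (1 + exp(b2 - c2 * x))^(1 / d),
    gompertz = y ~ a3 * exp(-c3 * exp(-b3 * x)))
}

#' Fit a sigmoidal growth model to relative LAI
#'
#' Bounded Levenberg-Marquardt nonlinear least squares (via
#' \code{minpack.lm::nlsLM}) with a deterministic five-point multi-start to
#' avoid local minima; the lowest-cost converged start wins.
#'
#' @param x Growth days since cut/sowing.
#' @param rlai Relative LAI observations (values slightly above 1 permitted).
#' @param kind `"logistic"`, `"richards"` or `"gompertz"`.
#' @param init Optional single starting parameter vector/list; replaces the
#'   multi-start grid.
#' @param lower,upper Optional bounds (numeric, in parameter order).
#' @param convention Richards convention; `"standard"` (default) is the
#'   monotone-increasing form.
#' @return A `growth_fit` object: `kind`, `params`, fit metrics (`r2` in the
#'   1 - SSres/SStot sense, `rmse`, `mae`), `rss` and `n_obs`.
#' @examples
#' x <- 1:70
#' y <- eval_logistic(logistic_params(2.42, -0.17, 3e-4), x)
#' fit_growth(x, y, "logistic")
#' @export
fit_growth <- function(x, rlai, kind = c("logistic", "richards", "gompertz"),
                       init = NULL, lower = NULL, upper = NULL,
                       convention = c("standard", "printed")) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  if (length(x) != length(rlai)) stop("`x` and `rlai` lengths differ", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(rlai)))
    stop("observations must be finite", call. = FALSE)
  npar <- .growth_npar[[kind]]
  if (length(x) < npar)
    stop(sprintf("under-determined fit: %d observations for %d parameters",
                 length(x), npar), call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("`x` values are all identical; the curve is not identifiable", call. = FALSE)

  bounds <- .growth_bounds(kind)
  if (!is.null(lower)) bounds$lower <- lower
  if (!is.null(upper)) bounds$upper <- upper
  starts <- if (is.null(init)) .growth_starts(kind) else {
    v <- unlist(init)
    if (length(v) != npar) stop("`init` has wrong length", call. = FALSE)
    names(v) <- names(.growth_starts(kind)[[1]])
    list(v)
  }

  dat <- data.frame(x = x, y = rlai)
  form <- .growth_formula(kind, convention)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-13)

  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, bounds$lower), bounds$upper)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(form, data = dat, start = as.list(st),
                                         lower = bounds$lower, upper = bounds$upper,
                                         control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop(sprintf("growth model fit did not converge for kind = '%s'", kind),
         call. = FALSE)

  coefs <- as.list(stats::coef(best$fit))
  params <- switch(kind,
    logistic = logistic_params(coefs$a1, coefs$b1, coefs$c1),
    richards = richards_params(coefs$a2, coefs$b2, coefs$c2, coefs$d),
    gompertz = gompertz_params(coefs$a3, coefs$b3, coefs$c3))
  res <- stats::residuals(best$fit)
  sst <- sum((rlai - mean(rlai))^2)
  structure(list(
    kind = kind, params = params, convention = convention,
    r2 = if (sst > 0) 1 - best$rss / sst else NA_real_,
    rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
    rss = best$rss, n_obs = length(x)
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s model (n = %d)\n", x$kind, x$n_obs))
  cat("  params:", paste(sprintf("%s = %.6g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  cat(sprintf("  R2 = %.4f, RMSE = %.4f, MAE = %.4f\n", x$r2, x$rmse, x$mae))
  invisible(x)
}

## ---- derivative analysis -------------------------------------------------

#' First derivative of a growth curve
#'
#' Analytic d(RLAI)/dx of the fitted (or supplied) model at `x`.
#'
#' @inheritParams eval_growth
#' @return Numeric vector of growth rates (RLAI per day).
#' @export
growth_rate <- function(fit, x, convention = NULL) {
  if (inherits(fit, "growth_fit")) {
    convention <- convention %||% fit$convention
    params <- fit$params; kind <- fit$kind
  } else {
    params <- fit; kind <- .params_kind(fit)
    convention <- convention %||% "standard"
  }
  p <- params
  switch(kind,
    logistic = {
      f <- eval_logistic(p, x)
      -(p$b1 + 2 * p$c1 * x) * f * (1 - f)
    },
    richards = {
      z <- .clamp_exp(p$b2 - p$c2 * x)
      ez <- exp(z)
      if (convention == "standard")
        (p$a2 * p$c2 / p$d) * ez * (1 + ez)^(-1 / p$d - 1)
      else
        -(p$a2 * p$c2 / p$d) * ez * (1 + ez)^(1 / p$d - 1)
    },
    gompertz = {
      f <- eval_gompertz(p, x)
      f * p$c3 * p$b3 * exp(.clamp_exp(-p$b3 * x))
    })
}

#' Day of fastest growth
#'
#' Argmax of [growth_rate()] over `[x_lo, x_hi]`: a 0.1-day grid scan followed
#' by local refinement of the bracketing interval. Deterministic; ties go to
#' the earliest day.
#'
#' @inheritParams eval_growth
#' @param range Numeric length-2 vector `c(x_lo, x_hi)` with `x_lo < x_hi`.
#' @return The day (numeric scalar) at which the growth rate is maximal.
#' @examples
#' fastest_growth_day(logistic_params(3, -0.15), c(0, 60))  # -a1/b1 = 20
#' @export
fastest_growth_day <- function(fit, range, convention = NULL) {
  stopifnot(length(range) == 2L, range[1] < range[2])
  grid <- seq(range[1], range[2], by = 0.1)
  if (grid[length(grid)] < range[2]) grid <- c(grid, range[2])
  r <- growth_rate(fit, grid, convention = convention)
  i <- which.max(r)
  lo <- max(range[1], grid[i] - 0.1)
  hi <- min(range[2], grid[i] + 0.1)
  ref <- stats::optimize(function(z) -growth_rate(fit, z, convention = convention),
                         lower = lo, upper = hi, tol = 1e-9)
  cand <- c(grid[i], ref$minimum, range[1], range[2])
  val <- growth_rate(fit, cand, convention = convention)
  # best rate; earliest day on (near-)ties
  keep <- which(val >= max(val) - 1e-12)
  min(cand[keep])
}

#' Daily LAI augmentation from a fitted curve
#'
#' Scales the fitted relative-LAI curve back to LAI units,
#' `LAI(day) = f(day) * lai_max`, producing one value per requested day. This
#' is how sparse 7-day field measurements are densified to a daily series.
#'
#' @inheritParams eval_growth
#' @param lai_max Measured maximum LAI (> 0) used as the scale factor.
#' @param days Integer (or numeric) vector of growth days; must be non-empty.
#' @return Numeric vector of LAI values, one per day.
#' @export
augment_daily <- function(fit, lai_max, days, convention = NULL) {
  if (length(days) == 0L) stop("`days` must be non-empty", call. = FALSE)
  if (!is.finite(lai_max) || lai_max <= 0)
    stop("`lai_max` must be positive", call. = FALSE)
  eval_growth(fit, days, convention = convention) * lai_max
}

#' Average growth-rate table across models
#'
#' Helper reproducing the discrete slope comparison used in per-cut analyses:
#' evaluates the first derivative of each supplied fit at a handful of growth
#' days and averages across models. Makes no claim about the argmax; use
#' [fastest_growth_day()] for that.
#'
#' @param fits A list of `growth_fit` (or `growth_params`) objects.
#' @param days Growth days at which to tabulate slopes.
#' @return A data.frame with one row per day, per-model slopes and their mean.
#' @export
growth_rate_table <- function(fits, days = c(15, 20, 25, 30, 35, 40)) {
  stopifnot(length(fits) >= 1L)
  slopes <- vapply(fits, function(f) growth_rate(f, days), numeric(length(days)))
  slopes <- matrix(slopes, nrow = length(days))
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  if (is.null(names(fits))) names(fits) <- nm
  out <- data.frame(day = days)
  for (j in seq_along(fits)) out[[nm[j]]] <- slopes[, j]
  out$mean_slope <- rowMeans(slopes)
  out
}
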