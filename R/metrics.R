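.check_pairs <- function(y_obs, y_pred) {
  if (length(y_obs) == 0L) stop("empty input", call. = FALSE)
  if (length(y_obs) != length(y_pred))
    stop("`y_obs` and `y_pred` lengths differ", call. = FALSE)
}

#' Forecast accuracy metrics
#'
#' Mean absolute error, root mean square error and the coefficient of
#' determination, all in the units of the observations.
#'
#' `r2()` computes two forms. The `"standard"` form is
#' `1 - SSres/SStot`, bounded above by 1. The `"printed"` form is the
#' explained-variance ratio `sum((pred - mean(obs))^2) / sum((obs -
#' mean(obs))^2)`, which is unbounded above; both are reported by
#' [metrics_report()] and `"standard"` is the package default wherever a
#' single number is needed.
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values (same length).
#' @return A scalar.
#' @examples
#' mae(c(1, 2, 3), c(2, 2, 5))   # 1
#' rmse(c(1, 2, 3), c(2, 2, 5))  # sqrt(5/3)
#' @export
mae <- function(y_obs, y_pred) {
  .check_pairs(y_obs, y_pred)
  mean(abs(y_pred - y_obs))
}

#' @rdname mae
#' @export
rmse <- function(y_obs, y_pred) {
  .check_pairs(y_obs, y_pred)
  sqrt(mean((y_pred - y_obs)^2))
}

#' @rdname mae
#' @param form Which coefficient of determination to return.
#' @export
r2 <- function(y_obs, y_pred, form = c("standard", "printed")) {
  form <- match.arg(form)
  .check_pairs(y_obs, y_pred)
  if (length(y_obs) < 2L) stop("need at least 2 pairs for R2", call. = FALSE)
  ybar <- mean(y_obs)
  sst <- sum((y_obs - ybar)^2)
  if (sst <= 0) stop("zero variance in observations; R2 undefined", call. = FALSE)
  if (form == "standard") 1 - sum((y_pred - y_obs)^2) / sst
  else sum((y_pred - ybar)^2) / sst
}

#' Bundle all metrics for a set of forecast pairs
#'
#' @inheritParams mae
#' @return A `metrics_report` list: `mae`, `rmse`, `r2_standard`,
#'   `r2_printed`, `n`. `rmse >= mae` always (quadratic vs arithmetic mean).
#' @export
metrics_report <- function(y_obs, y_pred) {
  structure(list(
    mae = mae(y_obs, y_pred),
    rmse = rmse(y_obs, y_pred),
    r2_standard = r2(y_obs, y_pred, "standard"),
    r2_printed = r2(y_obs, y_pred, "printed"),
    n = length(y_obs)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  MAE  = %.4f\n  RMSE = %.4f\n  R2   = %.4f (standard), %.4f (printed)\n",
              x$mae, x$rmse, x$r2_standard, x$r2_printed))
  invisible(x)
}
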