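# Delimited-text I/O for the daily LAI record schema:
#   DateTime,GDD,Growth days,Soil moisture 10,Soil moisture 20,Soil moisture 30,LAI

.lai_schema <- c("DateTime", "GDD", "Growth days", "Soil moisture 10",
                 "Soil moisture 20", "Soil moisture 30", "LAI")
.lai_cols <- c("date", "gdd", "growth_days", "sm10", "sm20", "sm30", "lai")

.norm_header <- function(h) tolower(gsub("[[:space:].]+", "", h))

.parse_lai_date <- function(s) {
  d <- as.Date(s, tryFormats = c("%Y/%m/%d", "%Y-%m-%d"), optional = TRUE)
  d
}

#' Read / write a daily LAI series
#'
#' Reads a CSV with the columns DateTime, GDD, Growth days, Soil moisture
#' 10/20/30 and LAI (header matching is case-, whitespace- and
#' punctuation-insensitive). Dates in `YYYY/M/D` or ISO `YYYY-M-D` form.
#' Rows are sorted by date; duplicate dates are an error. LAI may be missing
#' (empty/NA) on forecast-only rows; the other fields are validated
#' (`growth_days >= 0`, soil moisture within 0--100, `lai >= 0`).
#'
#' @param path File path.
#' @return A `lai_series` data.frame with columns `date`, `gdd`,
#'   `growth_days`, `sm10`, `sm20`, `sm30`, `lai`.
#' @export
read_lai_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e) stop("schema error: cannot parse '", path,
                                          "' as CSV (", conditionMessage(e), ")",
                                          call. = FALSE))
  hdr <- .norm_header(names(df))
  want <- .norm_header(.lai_schema)
  idx <- match(want, hdr)
  if (anyNA(idx)) {
    missing <- .lai_schema[is.na(idx)]
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- df[, idx]
  names(out) <- .lai_cols
  dates <- .parse_lai_date(as.character(out$date))
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop(sprintf("unparseable date '%s' at data row %d", out$date[bad], bad),
         call. = FALSE)
  }
  out$date <- dates
  for (cc in .lai_cols[-1]) out[[cc]] <- as.numeric(out[[cc]])
  if (anyDuplicated(out$date))
    stop("duplicate dates in input", call. = FALSE)
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  .validate_lai_series(out)
  structure(out, class = c("lai_series", "data.frame"))
}

.validate_lai_series <- function(df) {
  if (any(df$growth_days < 0, na.rm = TRUE))
    stop("growth_days must be >= 0", call. = FALSE)
  sm <- unlist(df[c("sm10", "sm20", "sm30")], use.names = FALSE)
  if (any(sm < 0 | sm > 100, na.rm = TRUE))
    stop("soil moisture must lie in [0, 100]", call. = FALSE)
  if (any(df$lai < 0, na.rm = TRUE))
    stop("lai must be >= 0 where present", call. = FALSE)
  invisible(df)
}

#' @rdname read_lai_csv
#' @param series A `lai_series` data.frame.
#' @export
write_lai_csv <- function(series, path) {
  stopifnot(is.data.frame(series), all(.lai_cols %in% names(series)))
  out <- series[.lai_cols]
  d <- as.POSIXlt(out$date)
  out$date <- sprintf("%d/%d/%d", d$year + 1900L, d$mon + 1L, d$mday)
  for (cc in .lai_cols[-1]) out[[cc]] <- round(as.numeric(out[[cc]]), 6)
  names(out) <- .lai_schema
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write detected change points as CSV
#'
#' Columns `index,date,statistic`: the 1-based sample index, the calendar
#' date of that sample (if a series is supplied) and the MOSUM statistic at
#' the detection peak.
#'
#' @param result A `mosum_result` from [detect_change_points()].
#' @param path Output file.
#' @param series Optional `lai_series` supplying dates.
#' @export
write_changepoints_csv <- function(result, path, series = NULL) {
  stopifnot(inherits(result, "mosum_result"))
  cps <- result$change_points
  stat <- if (length(result$peaks)) {
    R <- result$statistic
    # statistic at each selected peak, in original index alignment
    off <- if (result$config$detrend == "diff") 1L else 0L
    R[pmin(result$peaks + off, length(R))]
  } else numeric(0)
  df <- data.frame(index = cps,
                   date = if (!is.null(series)) as.character(series$date[cps])
                          else NA_character_,
                   statistic = round(stat, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
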