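#' Change-point set
#'
#' A validated container for detected (or true) change-point indices of a
#' series. Indices are 1-based sample positions, each interpreted as the
#' first index of the post-change regime.
#'
#' @param points Strictly increasing integer indices (may be empty).
#' @param n Series length.
#' @return A `change_point_set` list with fields `points` and `n`.
#' @export
change_point_set <- function(points, n) {
  n <- as.integer(n)
  points <- as.integer(points)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (length(points)) {
    if (any(points < 1L | points > n))
      stop("change points must lie in [1, n]", call. = FALSE)
    if (any(diff(points) <= 0L))
      stop("change points must be strictly increasing", call. = FALSE)
  }
  structure(list(points = points, n = n), class = "change_point_set")
}

.as_cps <- function(cps, n = NULL) {
  if (inherits(cps, "change_point_set")) return(cps)
  change_point_set(cps, n %||% (if (length(cps)) max(cps) else 1L))
}

#' Contiguous training window
#'
#' @param start First index (1-based).
#' @param end Last index (inclusive); give either `end` or `s`.
#' @param s Window length (`end = start + s - 1`).
#' @return A `window_sample` list with `start`, `end` and length `s`.
#' @export
window_sample <- function(start, end = NULL, s = NULL) {
  start <- as.integer(start)
  if (is.null(end) && is.null(s)) stop("give `end` or `s`", call. = FALSE)
  end <- if (is.null(end)) start + as.integer(s) - 1L else as.integer(end)
  if (start < 1L || end < start) stop("need 1 <= start <= end", call. = FALSE)
  structure(list(start = start, end = end, s = end - start + 1L),
            class = "window_sample")
}

#' Maximum change-point-free window length
#'
#' With two or more change points, half the smallest distance between
#' adjacent change points, floored (and raised to a minimum of 1). This
#' guarantees that between every adjacent pair at least one window of this
#' length fits without touching either point. With fewer than two points the
#' spacing rule is vacuous; `floor(n/4)` capped at `cap` is used so that many
#' distinct windows remain available.
#'
#' @param cps A [change_point_set()].
#' @param cap Upper bound used only in the < 2 change-point fallback.
#' @return Integer `s_max >= 1`.
#' @examples
#' max_batch_size(change_point_set(c(10, 20, 35), 50))  # min gap 10 -> 5
#' @export
max_batch_size <- function(cps, cap = 50L) {
  cps <- .as_cps(cps)
  if (length(cps$points) < 2L)
    return(max(1L, min(as.integer(cap), cps$n %/% 4L)))
  max(1L, min(diff(cps$points)) %/% 2L)
}

#' Does a window contain a change point?
#'
#' `TRUE` iff some change point `c` satisfies `start <= c <= end`. Windows may
#' end immediately before or start immediately at a change point's neighbour;
#' only covering the point itself disqualifies (no buffer margin).
#'
#' @param w A [window_sample()] (or list with `start` and `end`).
#' @param cps A [change_point_set()] or integer vector of points.
#' @return Logical scalar.
#' @export
window_contains_changepoint <- function(w, cps) {
  cps <- .as_cps(cps)
  any(cps$points >= w$start & cps$points <= w$end)
}

#' Enumerate all valid window starts
#'
#' Exactly the starts in `[1, n - s + 1 - margin]` whose window
#' `[start, start + s - 1 + margin]` excludes every change point. `margin`
#' extends the exclusion zone past the window end, e.g. `margin = 1` also
#' protects a one-step-ahead forecast target.
#'
#' @param n Series (or region) length.
#' @param s Window length, `1 <= s <= n`.
#' @param cps Change points ([change_point_set()] or integer vector).
#' @param margin Extra protected samples after the window end (default 0).
#' @return Sorted integer vector of valid starts (possibly empty).
#' @export
valid_starts <- function(n, s, cps, margin = 0L) {
  n <- as.integer(n); s <- as.integer(s); margin <- as.integer(margin)
  if (s < 1L) stop("`s` must be >= 1", call. = FALSE)
  if (s + margin > n) stop("window (plus margin) longer than series", call. = FALSE)
  cps <- .as_cps(cps, n)
  last <- n - s + 1L - margin
  ok <- rep(TRUE, last)
  w <- s + margin   # effective protected length
  for (p in cps$points) {
    lo <- max(1L, p - w + 1L)
    hi <- min(p, last)
    if (lo <= hi) ok[lo:hi] <- FALSE
  }
  which(ok)
}

#' Rejection-sample one change-point-free window
#'
#' Draws `start` uniformly from `[1, n - s + 1]` and redraws until the window
#' `[start, start + s - 1]` (plus `margin`) contains no change point.
#' Feasibility is checked up front via [valid_starts()], so the loop cannot
#' run forever; a retry cap additionally protects it (falling back to a
#' direct uniform draw from the valid set, which is the same distribution).
#'
#' @inheritParams valid_starts
#' @param max_retry Retry cap for the rejection loop.
#' @return A [window_sample()]. Uses R's global RNG stream.
#' @export
sample_valid_window <- function(n, s, cps, margin = 0L, max_retry = 1000L) {
  vs <- valid_starts(n, s, cps, margin)
  if (!length(vs))
    stop("no valid window: every candidate window contains a change point",
         call. = FALSE)
  cps <- .as_cps(cps, n)
  last <- as.integer(n) - as.integer(s) + 1L - as.integer(margin)
  for (i in seq_len(max_retry)) {
    start <- sample.int(last, 1L)
    w <- window_sample(start, s = as.integer(s) + as.integer(margin))
    if (!window_contains_changepoint(w, cps))
      return(window_sample(start, s = s))
  }
  window_sample(vs[sample.int(length(vs), 1L)], s = s)
}

#' Assemble minibatches of change-point-free windows
#'
#' One training epoch's worth of window starts: `batches_per_epoch`
#' minibatches of `minibatch_size` starts each, drawn uniformly (with
#' replacement) from the valid start set. With `filter = FALSE` the change
#' points are ignored (unrestricted baseline sampling).
#'
#' @inheritParams valid_starts
#' @param batches_per_epoch Number of minibatches (default: enough to cover
#'   the valid starts once, `ceiling(length(valid)/minibatch_size)`).
#' @param minibatch_size Windows per minibatch (>= 1).
#' @param filter If `FALSE`, sample from all in-range starts instead of the
#'   change-point-free set.
#' @return List of minibatches; each is a data.frame with `start` and `end`.
#'   Uses R's global RNG stream (seed it for reproducibility).
#' @export
make_training_batches <- function(n, s, cps, batches_per_epoch = NULL,
                                  minibatch_size = 32L, margin = 0L,
                                  filter = TRUE) {
  minibatch_size <- as.integer(minibatch_size)
  if (minibatch_size < 1L) stop("`minibatch_size` must be >= 1", call. = FALSE)
  vs <- if (filter) valid_starts(n, s, cps, margin)
        else seq_len(as.integer(n) - as.integer(s) + 1L - as.integer(margin))
  if (!length(vs))
    stop("no valid window: every candidate window contains a change point",
         call. = FALSE)
  if (is.null(batches_per_epoch))
    batches_per_epoch <- ceiling(length(vs) / minibatch_size)
  batches_per_epoch <- as.integer(batches_per_epoch)
  if (batches_per_epoch < 1L) stop("`batches_per_epoch` must be >= 1", call. = FALSE)
  lapply(seq_len(batches_per_epoch), function(b) {
    st <- vs[sample.int(length(vs), minibatch_size, replace = TRUE)]
    data.frame(start = st, end = st + as.integer(s) - 1L)
  })
}
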