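# Seeded simulator of multi-cut alfalfa growing seasons. Each year is tiled
# by `cuts_per_year` contiguous regrowth segments; within a segment the LAI
# follows a logistic curve of growth days scaled by that cut's peak LAI, and
# the first day of the next segment is the abrupt post-cutting drop.

#' Per-cut simulation settings
#'
#' @param length Days from regrowth start to cutting (>= 10).
#' @param params [logistic_params()] describing the relative-LAI curve of the
#'   cut as a function of growth days.
#' @param lai_max Peak LAI of the cut (> 0).
#' @return A `cut_spec` list.
#' @export
cut_spec <- function(length, params, lai_max) {
  length <- as.integer(length)
  if (length < 10L) stop("cut `length` must be >= 10 days", call. = FALSE)
  if (!is.finite(lai_max) || lai_max <= 0)
    stop("`lai_max` must be positive", call. = FALSE)
  params <- .as_params(params, "logistic")
  structure(list(length = length, params = params, lai_max = lai_max),
            class = "cut_spec")
}

# Default per-cut relative-LAI curves. Fastest-growth days ~32/23/20/18;
# the quadratic term on the fourth cut bends the canopy down late in the
# regrowth, mimicking the late-season decline.
.default_cut_params <- list(
  logistic_params(4.80, -0.15, 0),
  logistic_params(3.45, -0.15, 0),
  logistic_params(3.20, -0.16, 0),
  logistic_params(2.90, -0.17, 0.00155)
)
.default_cut_lengths <- c(115L, 90L, 85L, 75L)

#' Season simulation settings
#'
#' Defaults describe the standard two-year, four-cut daily fixture: segment
#' lengths 115/90/85/75 days tiling each 365-day year, per-cut peak LAI drawn
#' in roughly 3.5--6.5 (fourth cut about 5), growing degree days accumulated
#' above a 5 degC base from a sinusoidal temperature year, and AR(1) soil
#' moisture at three depths.
#'
#' @param years Number of simulated years.
#' @param cuts_per_year 3 or 4 cuts per year.
#' @param cut_lengths Integer vector (length `cuts_per_year`) of segment
#'   lengths; must sum to 365 so segments tile the year.
#' @param cut_params List of [logistic_params()], one per cut.
#' @param lai_max_range Matrix-like list: for each cut, `c(lo, hi)` bounds of
#'   the uniform draw of that cut's peak LAI (drawn once per cut per year).
#' @param base_temp GDD base temperature (degC).
#' @param temp_mean,temp_amplitude,temp_phase Annual temperature sinusoid:
#'   mean, half-amplitude (degC) and day-of-year of the warm peak.
#' @param temp_noise_sd Daily temperature noise s.d. (degC).
#' @param sm_mean,sm_ar1,sm_sigma Soil-moisture AR(1) process per depth:
#'   means (%, length 3), a common autoregression coefficient in [0, 1) and
#'   innovation s.d. (%).
#' @param obs_noise_sigma LAI measurement noise s.d. (LAI units, >= 0).
#' @param sampling `"daily"` or `"7day"` observation cadence.
#' @param start_date First calendar day of the series.
#' @param seed Integer seed; the simulation is fully reproducible per seed.
#' @return A `season_config` list.
#' @export
season_config <- function(years = 2L, cuts_per_year = 4L,
                          cut_lengths = NULL, cut_params = NULL,
                          lai_max_range = NULL,
                          base_temp = 5, temp_mean = 12, temp_amplitude = 14,
                          temp_phase = 200, temp_noise_sd = 1.5,
                          sm_mean = c(24, 25, 23), sm_ar1 = 0.95,
                          sm_sigma = 0.6, obs_noise_sigma = 0.05,
                          sampling = c("daily", "7day"),
                          start_date = as.Date("2017-01-01"), seed = 42L) {
  sampling <- match.arg(sampling)
  years <- as.integer(years); cuts_per_year <- as.integer(cuts_per_year)
  if (!cuts_per_year %in% c(3L, 4L))
    stop("`cuts_per_year` must be 3 or 4", call. = FALSE)
  if (is.null(cut_lengths)) {
    cut_lengths <- if (cuts_per_year == 4L) .default_cut_lengths
                   else c(140L, 120L, 105L)
  }
  cut_lengths <- as.integer(cut_lengths)
  if (length(cut_lengths) != cuts_per_year)
    stop("`cut_lengths` must have one entry per cut", call. = FALSE)
  if (any(cut_lengths < 10L))
    stop("infeasible cut schedule: every cut needs >= 10 days", call. = FALSE)
  if (sum(cut_lengths) != 365L)
    stop("infeasible cut schedule: segment lengths must tile the 365-day year",
         call. = FALSE)
  if (is.null(cut_params))
    cut_params <- .default_cut_params[seq_len(cuts_per_year)]
  if (length(cut_params) != cuts_per_year)
    stop("`cut_params` must have one entry per cut", call. = FALSE)
  if (is.null(lai_max_range)) {
    lai_max_range <- rep(list(c(3.5, 6.5)), cuts_per_year)
    if (cuts_per_year == 4L) lai_max_range[[4L]] <- c(4.8, 5.2)
  }
  if (!(sm_ar1 >= 0 && sm_ar1 < 1)) stop("`sm_ar1` must be in [0, 1)", call. = FALSE)
  if (obs_noise_sigma < 0) stop("`obs_noise_sigma` must be >= 0", call. = FALSE)
  structure(list(years = years, cuts_per_year = cuts_per_year,
                 cut_lengths = cut_lengths, cut_params = cut_params,
                 lai_max_range = lai_max_range, base_temp = base_temp,
                 temp_mean = temp_mean, temp_amplitude = temp_amplitude,
                 temp_phase = temp_phase, temp_noise_sd = temp_noise_sd,
                 sm_mean = sm_mean, sm_ar1 = sm_ar1, sm_sigma = sm_sigma,
                 obs_noise_sigma = obs_noise_sigma, sampling = sampling,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "season_config")
}

#' Simulate a multi-cut LAI season
#'
#' Generates the daily series and the true change points (the first day of
#' every regrowth segment after the first, i.e. the day the canopy has just
#' been cut). Noise-free generation (`obs_noise_sigma = 0`) returns exactly
#' the logistic curve times each cut's peak LAI.
#'
#' @param config A [season_config()].
#' @return A list: `series` (a `lai_series` data.frame), `change_points`
#'   (a [change_point_set()]), and `truth` (per-day noise-free LAI plus the
#'   per-segment peak LAI actually drawn).
#' @export
simulate_dataset <- function(config = season_config()) {
  stopifnot(inherits(config, "season_config"))
  set.seed(config$seed)
  nseg_year <- config$cuts_per_year
  lengths <- rep(config$cut_lengths, config$years)
  cut_of_seg <- rep(seq_len(nseg_year), config$years)
  nseg <- length(lengths)
  n <- sum(lengths)

  # peak LAI per segment
  lai_max_seg <- vapply(seq_len(nseg), function(i) {
    rg <- config$lai_max_range[[cut_of_seg[i]]]
    stats::runif(1, rg[1], rg[2])
  }, numeric(1))

  growth_days <- unlist(lapply(lengths, seq_len), use.names = FALSE)
  seg_id <- rep(seq_len(nseg), lengths)
  rlai <- numeric(n)
  for (i in seq_len(nseg)) {
    sel <- seg_id == i
    rlai[sel] <- eval_logistic(config$cut_params[[cut_of_seg[i]]],
                               growth_days[sel])
  }
  lai_true <- rlai * lai_max_seg[seg_id]
  lai_obs <- pmax(0, lai_true + stats::rnorm(n, 0, config$obs_noise_sigma))

  # thermal time: sinusoidal year + noise, accumulated above base, reset per cut
  dates <- config$start_date + 0:(n - 1L)
  doy <- as.integer(format(dates, "%j"))
  temp <- config$temp_mean +
    config$temp_amplitude * cos(2 * pi * (doy - config$temp_phase) / 365) +
    stats::rnorm(n, 0, config$temp_noise_sd)
  gdd_day <- pmax(0, temp - config$base_temp)
  gdd <- stats::ave(gdd_day, seg_id, FUN = cumsum)

  # exogenous AR(1) soil moisture per depth
  sm <- sapply(1:3, function(j) {
    e <- stats::rnorm(n, 0, config$sm_sigma)
    z <- numeric(n)
    z[1] <- config$sm_mean[j] + e[1] / sqrt(1 - config$sm_ar1^2)
    for (t in 2:n)
      z[t] <- config$sm_mean[j] + config$sm_ar1 * (z[t - 1] - config$sm_mean[j]) + e[t]
    pmin(100, pmax(0, z))
  })

  series <- data.frame(date = dates, gdd = gdd, growth_days = growth_days,
                       sm10 = sm[, 1], sm20 = sm[, 2], sm30 = sm[, 3],
                       lai = lai_obs)
  cps <- cumsum(lengths)[-nseg] + 1L   # first day of each later segment

  if (config$sampling == "7day") {
    keep <- seq(1L, n, by = 7L)
    series <- series[keep, , drop = FALSE]
    rownames(series) <- NULL
    cps <- vapply(cps, function(p) which.min(abs(keep - p)), integer(1))
    n <- length(keep)
  }
  list(series = structure(series, class = c("lai_series", "data.frame")),
       change_points = change_point_set(cps, n),
       truth = list(lai_true = lai_true, lai_max = lai_max_seg,
                    segment = seg_id))
}

#' The standard synthetic fixture
#'
#' Two years of daily records (730 rows), four cuts per year, seed 42 —
#' eight regrowth segments and exactly seven internal change points. Used
#' throughout the tests and the acceptance script.
#'
#' @param seed Seed (default 42).
#' @return Same structure as [simulate_dataset()].
#' @export
default_fixture <- function(seed = 42L) {
  simulate_dataset(season_config(seed = seed))
}
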