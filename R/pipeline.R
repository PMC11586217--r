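#' Pipeline configuration
#'
#' A declarative description of one end-to-end run: where the data come from
#' (a CSV in the daily LAI schema, or the built-in simulator), the
#' change-point detector settings, and the forecaster settings. All defaults
#' are embedded; [pipeline_config()] with no arguments describes the
#' standard synthetic run.
#'
#' @param data List: `source` (`"simulate"` or `"csv"`), `path` (CSV path
#'   when `source = "csv"`), and any [season_config()] overrides under
#'   `simulate`.
#' @param detect List of [mosum_config()] overrides.
#' @param model List of [network_config()] overrides.
#' @param seed Master seed; seeds the simulator and the network unless they
#'   carry their own.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = list(), detect = list(), model = list(),
                            seed = 42L) {
  structure(list(
    data = utils::modifyList(list(source = "simulate", path = NULL,
                                  simulate = list()), data),
    detect = detect, model = model, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with optional `data`, `detect`, `model`, `seed`
#'   sections.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(data = y$data %||% list(), detect = y$detect %||% list(),
                  model = y$model %||% list(), seed = y$seed %||% 42L)
}

#' Write the fully-resolved default configuration to YAML
#'
#' @param path Output path.
#' @export
write_default_config <- function(path) {
  cfg <- pipeline_config()
  sc <- season_config()
  nc <- network_config()
  mc <- mosum_config()
  yaml::write_yaml(list(
    seed = cfg$seed,
    data = list(source = "simulate", path = NULL,
                simulate = list(years = sc$years, cuts_per_year = sc$cuts_per_year,
                                obs_noise_sigma = sc$obs_noise_sigma,
                                sampling = sc$sampling)),
    detect = list(k = mc$k, G = mc$G, threshold_mode = mc$threshold_mode,
                  threshold_value = mc$threshold_value, detrend = mc$detrend),
    model = list(variant = nc$variant, hidden = nc$hidden,
                 lr = nc$lr, minibatch = nc$minibatch,
                 max_epochs = nc$max_epochs, patience = nc$patience)
  ), path)
  invisible(path)
}

# Tiny stable polynomial rolling hash of the serialized config, for
# artifact stamping.
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full forecasting pipeline
#'
#' Stages, in order: simulate or load the daily series; detect change points
#' with MOSUM; plan the window budget (`s_max`); train the configured
#' forecaster with change-point-aware batching; forecast the test split; and
#' evaluate. When `out_dir` is given, the artifacts are written there:
#' `change_points.csv`, `model.json`, `predictions.csv`, `metrics.json` and
#' `config.json` (each stamped with the config hash and seed).
#'
#' @param config A [pipeline_config()], or the path to a YAML file.
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `series`, `detection`, `s_max`, `model`,
#'   `forecast` and `metrics`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- .config_hash(config)

  # -- stage: data
  if (identical(config$data$source, "simulate")) {
    sim_args <- config$data$simulate %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sc <- do.call(season_config, sim_args)
    sim <- simulate_dataset(sc)
    series <- sim$series
    say("[data] simulated %d daily records (%d true change points)",
        nrow(series), length(sim$change_points$points))
  } else if (identical(config$data$source, "csv")) {
    if (is.null(config$data$path)) stop("data stage: `path` required for csv source",
                                        call. = FALSE)
    series <- read_lai_csv(config$data$path)
    say("[data] read %d records from %s", nrow(series), config$data$path)
  } else stop("data stage: unknown source '", config$data$source, "'",
              call. = FALSE)

  # -- stage: detect
  mc <- do.call(mosum_config, config$detect)
  det <- tryCatch(detect_change_points(series$lai, mc),
                  error = function(e) stop("detect stage: ",
                                           conditionMessage(e), call. = FALSE))
  cps <- change_point_set(det$change_points, nrow(series))
  say("[detect] %d change point(s) at threshold %.4g",
      length(cps$points), det$threshold)

  # -- stage: plan batches
  s_max <- max_batch_size(cps)
  say("[plan] s_max = %d", s_max)

  # -- stage: train
  margs <- config$model
  if (is.null(margs$seed)) margs$seed <- config$seed
  nc <- tryCatch(do.call(network_config, margs),
                 error = function(e) stop("train stage: ",
                                          conditionMessage(e), call. = FALSE))
  model <- tryCatch(train_lai_model(series, cps, nc),
                    error = function(e) stop("train stage: ",
                                             conditionMessage(e), call. = FALSE))
  say("[train] %s variant: %d epochs, best validation MSE %.5g",
      nc$variant, if (nrow(model$history)) max(model$history$epoch) else 0L,
      if (nrow(model$history)) min(model$history$val_loss) else NA)

  # -- stage: predict + evaluate
  fc <- tryCatch(predict_series(model, series),
                 error = function(e) stop("predict stage: ",
                                          conditionMessage(e), call. = FALSE))
  say("[evaluate] test split: R2 = %.4f, RMSE = %.4f, MAE = %.4f",
      fc$metrics$r2_standard, fc$metrics$rmse, fc$metrics$mae)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_changepoints_csv(det, file.path(out_dir, "change_points.csv"), series)
    save_lai_model(model, file.path(out_dir, "model.json"))
    pred <- data.frame(date = as.character(fc$date),
                       observed = round(fc$observed, 6),
                       predicted = round(fc$predicted, 6))
    utils::write.csv(pred, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(
      config_hash = hash, seed = config$seed, variant = nc$variant,
      s_max = s_max, window = model$window,
      n_change_points = length(cps$points),
      epochs_run = if (nrow(model$history)) max(model$history$epoch) else 0L,
      metrics = unclass(fc$metrics)
    ), file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(c(list(config_hash = hash), unclass(config)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
    say("[artifacts] written to %s (config %s)", out_dir, hash)
  }

  invisible(list(series = series, detection = det, change_points = cps,
                 s_max = s_max, model = model, forecast = fc,
                 metrics = fc$metrics, config_hash = hash))
}

#' Variant comparison on one dataset
#'
#' Trains the requested variants over several seeds on the same series and
#' change points, and reports per-run and median test-split metrics —
#' the scaled-down analogue of the usual LSTM / BiLSTM / MOSUM-filtered /
#' attention-encoder-decoder comparison.
#'
#' @param series A `lai_series` (default: the standard synthetic fixture).
#' @param cps Change points; `NULL` detects them from `series$lai`.
#' @param variants Character vector of variants to run.
#' @param seeds Integer vector of training seeds.
#' @param ... [network_config()] overrides applied to every run (e.g.
#'   `max_epochs = 100`).
#' @return A list: `runs` (one row per variant x seed with test metrics) and
#'   `summary` (per-variant medians).
#' @export
run_ablation <- function(series = NULL, cps = NULL,
                         variants = c("lstm", "bilstm", "mlstm", "mbilstm", "tmead"),
                         seeds = c(1L, 2L, 3L), ...) {
  if (is.null(series)) {
    fx <- default_fixture()
    series <- fx$series
    if (is.null(cps)) cps <- fx$change_points
  }
  if (is.null(cps)) {
    det <- detect_change_points(series$lai)
    cps <- change_point_set(det$change_points, nrow(series))
  }
  runs <- do.call(rbind, lapply(variants, function(v) {
    do.call(rbind, lapply(seeds, function(sd) {
      cfg <- network_config(variant = v, seed = sd, ...)
      mdl <- train_lai_model(series, cps, cfg)
      fc <- predict_series(mdl, series)
      data.frame(variant = v, seed = sd,
                 r2_standard = fc$metrics$r2_standard,
                 rmse = fc$metrics$rmse, mae = fc$metrics$mae,
                 epochs = if (nrow(mdl$history)) max(mdl$history$epoch) else 0L)
    }))
  }))
  summary <- do.call(rbind, lapply(split(runs, runs$variant), function(df) {
    data.frame(variant = df$variant[1],
               r2_standard = stats::median(df$r2_standard),
               rmse = stats::median(df$rmse), mae = stats::median(df$mae))
  }))
  summary <- summary[match(variants, summary$variant), ]
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}
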