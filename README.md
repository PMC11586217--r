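# laicast

Change-point-aware forecasting of alfalfa leaf area index (LAI).

Multi-harvest forage crops such as alfalfa (*Medicago sativa* L.) are cut
three to four times per season. Within each regrowth period the canopy's
leaf area index follows a sigmoid in growth days; at every cutting it
collapses abruptly. Those two regimes break the usual tools: classical
growth curves cannot use environmental covariates, and recurrent neural
forecasters are destabilized by the cutting discontinuities ("mutation
points") in their training windows.

`laicast` is an R package for people modelling canopy growth in such
systems — agronomists densifying sparse field LAI campaigns with fitted
curves, and forecasters training covariate-driven models on multi-cut
series. It provides:

* **Growth models** — Logistic, Richards and Gompertz curves of relative
  LAI (`RLAI = LAI / LAI_max`), e.g.
  `RLAI = 1/(1 + exp(a1 + b1*x + c1*x^2))` with `x` growth days; bounded
  multi-start nonlinear least squares, analytic derivatives, day of
  fastest growth, and daily augmentation `LAI(day) = f(day) * LAI_max`.
* **MOSUM change-point detection** — the moving-sum statistic
  `S_t = sum(x[(t-k+1):t])`, `R_t = S_t - S_{t-G}`, with a robust
  noise-scaled threshold `3 * sigma_hat * sqrt(2k)`, locates cutting
  events.
* **Change-point-aware batching** — the maximum window length
  `s_max = floor(min_gap / 2)` and uniform rejection sampling of
  contiguous training windows that contain no change point.
* **An attention BiLSTM encoder–decoder** (plus LSTM/BiLSTM baselines,
  with and without the change-point filter), hand-written in vectorised
  base R with gradient-checked backpropagation, trained with Adam, early
  stopping, and chronological train/validation/test splits.
* **A seeded season simulator** — multi-cut sigmoidal LAI with abrupt
  cutting drops, growing degree days from a sinusoidal temperature year,
  and AR(1) soil-moisture covariates — so the whole pipeline runs and is
  tested without any field data.

See `vignettes/laicast-methods.Rmd` for the models, assumptions, and
design choices.

## Worked example

```r
library(laicast)

# two simulated years, four cuts per year, daily records, seed 42
fx <- default_fixture()

# locate the cutting events
det <- detect_change_points(fx$series$lai)
det
#> <mosum_result> k = 5, G = 5, detrend = diff
#>   threshold = 0.8351 (sigma_hat = 0.08803)
#>   7 change point(s): 116, 206, 291, 366, 481, 571, 656
```

The detector recovers the simulator's seven cutting days exactly: the
threshold is calibrated from the noise scale of the differenced series,
and each peak of `|R_t|` is localized to the first post-cut sample.

```r
# train the attention encoder-decoder with change-point-free minibatches
cfg <- network_config(variant = "tmead", max_epochs = 100, seed = 1)
model <- train_lai_model(fx$series, NULL, cfg)   # NULL -> detect internally
fc <- predict_series(model, fx$series)
fc
#> <lai_forecast> 117 one-step forecasts
#> <metrics_report> n = 117
#>   MAE  = 0.2062
#>   RMSE = 0.2448
#>   R2   = 0.9505 (standard), 0.8826 (printed)
```

The forecast slides one-step-ahead windows across the held-out last 20%
of the series, scoring within regrowth segments (cutting dates are known
management events, not forecast targets). MAE/RMSE are in LAI units; both
coefficient-of-determination conventions are reported, and 0.95 of the
test-split LAI variance is explained.

```r
# per-cut growth analysis of the first regrowth segment
rl <- compute_rlai(fx$series$lai[1:115])
fit <- fit_growth(fx$series$growth_days[1:115], rl, "logistic")
fit
#> <growth_fit> logistic model (n = 115)
#>   params: a1 = 5.95972, b1 = -0.226191, c1 = 0.00124549
#>   R2 = 0.9989, RMSE = 0.0121, MAE = 0.0097
fastest_growth_day(fit, c(0, 115))
#> [1] 30.48612
```

The first cut's canopy grows fastest around day 30, consistent with the
slow first regrowth of spring.

A command-line front end over the same functions is installed as
`exec/laicast` (subcommands `simulate`, `detect`, `fit-growth`,
`plan-batches`, `train`, `predict`, `evaluate`, `ablation`,
`init-config`, `run`).

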