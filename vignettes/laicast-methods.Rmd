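---
title: "Methods: change-point-aware forecasting of multi-cut canopy growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: change-point-aware forecasting of multi-cut canopy growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(laicast)
```

## The problem

Alfalfa and other multi-harvest forage crops are cut several times per
season. The leaf area index (LAI) — one-sided leaf area per unit ground
area — grows along a sigmoid during each regrowth period and collapses
abruptly at every cutting. Forecasting LAI from daily covariates (thermal
time, days since cut, soil moisture) therefore mixes two very different
regimes: smooth within-cut growth, and rare, large, management-driven
discontinuities. Recurrent forecasters trained naively on such series spend
much of their capacity absorbing the discontinuities; classical growth
curves handle the shape but cannot use covariates at all.

`laicast` implements both families and the machinery connecting them:

1. sigmoidal growth models of *relative* LAI (RLAI = LAI / LAI~max~) with
   bounded multi-start least squares, derivative analysis and daily
   augmentation;
2. MOSUM (moving-sum) change-point detection of cutting events;
3. change-point-aware sampling of contiguous training windows;
4. a bidirectional LSTM encoder–decoder with a dot-product attention
   bridge, trained with Adam on mean squared error;
5. a seeded simulator of multi-cut seasons so that everything above is
   testable without field data.

## Growth models

The three classical forms, with `x` = growth days since cut:

* Logistic: $\mathrm{RLAI} = 1/(1 + e^{a_1 + b_1 x + c_1 x^2})$. The
  quadratic term allows a late-season downturn (`c1 > 0`).
* Richards: $\mathrm{RLAI} = a_2 (1 + e^{b_2 - c_2 x})^{-1/d}$ in the
  package's `"standard"` convention. A variant spelling with exponent
  $+1/d$ circulates in the applied literature; for $c_2 > 0$ that form is
  monotone *decreasing* and cannot describe regrowth, so the package fits
  the standard form by default and keeps the other behind
  `convention = "printed"` purely for comparability.
* Gompertz: $\mathrm{RLAI} = a_3 e^{-c_3 e^{-b_3 x}}$.

Fitting uses Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) from five deterministic starting points spread over
the plausible magnitude range (midpoints 15–35 days, rates 0.1–0.3 per
day), keeping the converged fit with the lowest residual sum of squares.
Bounds keep the Richards shape parameter away from zero. On noise-free
model-generated data the generating coefficients are recovered to a
relative error below 1e-4 (this is a test invariant).

The day of fastest growth is the argmax of the analytic first derivative,
located by a 0.1-day grid scan plus local refinement; closed forms
($-a_1/b_1$ for the symmetric logistic, $\ln(c_3)/b_3$ for Gompertz) are
used as test oracles. `growth_rate_table()` reproduces the discrete
"average slope at days 15–40 across the three models" style of analysis
but deliberately makes no argmax claim: averaging slopes at six discrete
days is too coarse to define an inflection point, so the package treats it
as a reporting helper only.

`augment_daily()` maps a fitted RLAI curve back to LAI units,
`LAI(day) = f(day) · LAI_max`, which is how sparse 7-day field measurements
are densified to a daily training series.

## Change-point detection

The MOSUM statistic compares adjacent window sums:
$S_t = \sum_{i=t-k+1}^{t} X_i$, $R_t = S_t - S_{t-G}$, with window `k` and
bandwidth `G` (default `k = G = 5`; the difference then reduces to the
classical single-bandwidth MOSUM). $R_t$ is reported only where both
windows are fully defined — padding would fabricate statistics.

Two numerical choices matter and are worth stating plainly:

* **Detection runs on first differences by default** (`detrend = "diff"`).
  The LAI series is piecewise-smooth, not piecewise-constant: during a fast
  regrowth phase the trend alone drives $|R_t|$ to roughly $k^2 \times$
  slope, far above any noise-scale threshold, so raw-series detection would
  flag every growth spurt. On the differenced series everything except the
  cutting drops lives at noise/curvature scale and a noise-calibrated
  threshold separates cleanly. `detrend = "none"` remains available for
  genuinely piecewise-constant signals.
* **The threshold is noise-scaled**: $3 \,\hat\sigma \sqrt{2k}$, where
  $\hat\sigma$ is the median absolute deviation of the first differences of
  the detection input divided by $\sqrt{2}\cdot 0.6745$ — a robust
  estimator that ignores the (rare) jumps themselves. An absolute mode
  exists for exact test control.

Candidate change points are local maxima of $|R_t|$ above the threshold,
selected greedily in decreasing magnitude subject to a minimum separation
of `2·max(k, G) + 1` samples (the statistic's response to one shift spans
up to `2k` samples; anything tighter can report a single cutting twice).
Ties break toward the earliest index. Localization is two-stage: the
selected peak flags a region, then the reported index — always the first
sample of the post-change regime — is pinned within the peak's response
support. In raw mode the peak of a clean level shift sits exactly at
`t = b + k − 1`, so the window start `t − k + 1` is exact; in diff mode the
shift is a single impulse in the differenced series and the largest
single-step change within the support locates it.

On the standard synthetic fixture the default detector finds all seven
cutting boundaries exactly, with no false positives.

## Change-point-aware window sampling

Training samples are contiguous windows `[start, start + s − 1]`. Windows
containing a cutting event mix regimes and poison the regression, so:

* `max_batch_size()` bounds the window length by half the smallest gap
  between adjacent change points — guaranteeing that at least one admissible
  window fits strictly inside every gap. With fewer than two points the rule
  is vacuous and `floor(n/4)` (capped at 50) is used instead, preserving
  many distinct windows.
* `sample_valid_window()` draws starts uniformly and rejects windows
  covering a change point. Feasibility is pre-checked by enumeration
  (`valid_starts()`), so the loop cannot spin forever; rejection sampling
  provably preserves uniformity over the valid set (a chi-square test
  asserts this).
* A window is admissible for training only if the window *and* its
  one-step forecast target are change-point-free (`margin = 1`). The
  alternative — protecting only the window — would still feed the network
  targets sitting on the far side of a cut.
* The start range is `[1, n − s + 1]` (1-based), i.e. the last fully
  contained window is admissible.

No buffer beyond the point itself is excluded (configurable `margin`), and
windows are not stratified across cuts.

## The forecaster

Five variants share one training loop:

| variant   | architecture                         | training windows        |
|-----------|--------------------------------------|-------------------------|
| `lstm`    | unidirectional LSTM + head           | unrestricted            |
| `bilstm`  | BiLSTM + head                        | unrestricted            |
| `mlstm`   | unidirectional LSTM + head           | change-point-free       |
| `mbilstm` | BiLSTM + head                        | change-point-free       |
| `tmead`   | BiLSTM encoder–attention–decoder     | change-point-free       |

The `tmead` encoder runs forward and backward LSTM passes over the scaled
window and concatenates per-step states. Attention scores each step by the
inner product of its forward and backward states, softmax-normalizes, and
averages the encoder outputs into a context vector — a static (query-free)
attention, implemented as specified rather than "fixed" into a
decoder-queried one. The single-step bidirectional decoder consumes the
final window step's covariates concatenated with the context; a fully
connected head (ReLU, then linear) maps the concatenated decoder states to
the prediction. ReLU sits on the head, not inside the recurrent cells,
whose gates keep their standard sigmoid/tanh nonlinearities.

All forward *and* backward passes are written in vectorised base-R matrix
algebra; correctness of every gradient is asserted against central finite
differences in the test suite (worst observed discrepancy ~1e-10).

Training details: features (GDD, growth days, three soil-moisture depths,
and the current LAI) are min-max scaled to [0, 1] on the training region
only; the target is scaled with the LAI bounds. Splits are chronological —
last 20% test, and of the remainder the last 20% is validation. Loss is
mean squared error (consistent with RMSE reporting), optimized by Adam at
learning rate 6e-4 with minibatches of 32 windows, at most 300 epochs,
early stopping with patience 20 and best-weight restoration. The default
window length is `min(14, s_max)`: with daily records, two weeks spans a
full growth phase while respecting the change-point budget. Seeds control
parameter initialization and window sampling; identical seeds reproduce
identical models bit for bit (single-threaded, deterministic kernels).

### Evaluation protocol

`predict_series()` slides one-step forecasts across the test split. By
default it scores only windows that lie within one regrowth segment
(window plus target free of change points), for *every* variant alike.
Cutting events are scheduled management interventions — the harvest date
is known, not forecast — so asking any of these models to predict through
a cut measures out-of-distribution extrapolation rather than forecasting
skill, and a handful of such windows would dominate R² on a split
containing a single cut. The switch `exclude_changepoints = FALSE` scores
through-cut windows too, and explicitly supplied window starts are never
filtered.

## The season simulator

`simulate_dataset()` emulates a multi-cut field campaign: each 365-day
year is tiled by four regrowth segments (115/90/85/75 days — first
regrowth slowest, later cuts faster, fastest-growth days ≈ 32/23/20/18);
within a segment LAI follows a per-cut logistic curve times a per-cut peak
LAI drawn uniformly (cuts 1–3 in 3.5–6.5, cut 4 in 4.8–5.2), plus Gaussian
observation noise (σ = 0.05 LAI units, truncated at zero); the first day
of the next segment is the cutting drop. The fourth cut carries a positive
quadratic term so its canopy declines late in the season. Thermal time
accumulates daily max(0, T − 5 °C) from a sinusoidal temperature year
(mean 12 °C, half-amplitude 14 °C, peak at day 200, daily noise 1.5 °C),
resetting at each cut. Soil moisture at the three depths follows
stationary AR(1) processes (means 24/25/23 %, coefficient 0.95, innovation
s.d. 0.6 %), exogenous to LAI — the coupling is deliberately absent so the
ground truth stays analytic. `default_fixture()` fixes seed 42: 730 daily
rows, eight segments, exactly seven internal change points.

What the simulator does *not* emulate: multiple plots under different
water/nitrogen treatments, weather reanalysis, a mechanistic soil water
balance, or any feedback from moisture to growth. Passing tests therefore
demonstrate the pipeline's correctness and the *relative* behaviour of its
variants under controlled conditions — not field-level accuracy.

## Scaled-down experiments

`run_ablation()` trains the five variants over several seeds on the
fixture and reports per-variant median test metrics. With 12 hidden units,
window `min(14, s_max)`, 100-epoch budget and seeds 1–3 (the sizes used in
the test suite, small enough to run on one CPU in a few minutes), the
medians reproduce the expected ordering: the change-point-filtered
variants beat their unfiltered counterparts, and the attention
encoder–decoder is the strongest filtered model, with test-split R²
(standard form) above 0.9. The per-cut error structure behind this is
instructive: on within-segment windows the filtered models are clearly
more accurate, while unfiltered models spend capacity on the cut
transitions.

Two coefficient-of-determination conventions circulate for such tables:
the explained-variance ratio $\sum(\hat y_i - \bar y)^2 / \sum(y_i - \bar
y)^2$ (which can exceed 1) and the standard $1 - SS_{res}/SS_{tot}$. Both
are computed (`r2_printed`, `r2_standard`); thresholds and comparisons in
this package always use the standard form, which is the only one bounded
above.

## Known limitations

* The forecaster is one-step-ahead only (`horizon = 1`); multi-step
  decoding would need a defined covariate path for future steps.
* Cut days themselves are not forecast — by design the method treats them
  as known management events; a deployment would read them from the
  harvest calendar.
* The printed Richards convention is evaluable but should not be fitted to
  growth data (it is monotone-decreasing for positive rates).
* Training is CPU-bound pure R; it is comfortable at the fixture's scale
  (seconds per hundred epochs) but not meant for thousands of features.
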