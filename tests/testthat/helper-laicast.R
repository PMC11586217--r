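# Shared fixtures and brute-force oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

# The standard synthetic dataset (2 years daily, 8 segments, 7 cut
# boundaries, seed 42), computed once per test run.
std_fixture <- function() {
  if (is.null(.fixture_cache$fx)) .fixture_cache$fx <- default_fixture()
  .fixture_cache$fx
}

# A small one-year series for fast network smoke tests.
small_fixture <- function() {
  if (is.null(.fixture_cache$small))
    .fixture_cache$small <- simulate_dataset(season_config(years = 1L, seed = 7L))
  .fixture_cache$small
}

# O(n*k) brute-force window sums, the independent oracle for moving_sum().
brute_moving_sum <- function(x, k) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in k:n) out[t] <- sum(x[(t - k + 1):t])
  out
}

brute_mosum <- function(x, k, G) {
  S <- brute_moving_sum(x, k)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in (k + G):n) out[t] <- S[t] - S[t - G]
  out
}

# Exhaustive enumeration of change-point-free windows (oracle for
# valid_starts / max_batch_size).
brute_valid_starts <- function(n, s, points) {
  keep <- integer(0)
  for (st in seq_len(n - s + 1)) {
    if (!any(points >= st & points <= st + s - 1)) keep <- c(keep, st)
  }
  keep
}

# Central-difference derivative oracle.
num_deriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)
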