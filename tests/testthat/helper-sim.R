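# Shared fixtures, all built in code.

# A cycle series straight from a vector of durations (for CORC-level tests
# that do not need a waveform).
series_from_durations <- function(d, amplitude = 8) {
  onset <- if (length(d)) cumsum(c(0, d[-length(d)])) else numeric(0)
  df <- data.frame(onset = onset, ti = 0.35 * d, te = 0.65 * d, duration = d,
                   amplitude = rep_len(amplitude, length(d)),
                   end_exp = rep_len(0, length(d)),
                   artifact = rep_len(FALSE, length(d)))
  structure(df, total_duration = sum(d), sample_rate = 1000,
            class = c("cycle_series", "data.frame"))
}

# Bimodal duration mixture: regular breathing plus a fraction of long
# isolated cycles (apneic cycles are kept non-adjacent).
bimodal_durations <- function(n = 600, p_apneic = 0.05, mu = 0.4, sd = 0.02,
                              lo = 2, hi = 5) {
  d <- pmax(0.1, stats::rnorm(n, mu, sd))
  k <- max(1L, round(p_apneic * n))
  pos <- sort(sample(seq(2, n - 1, by = 2), k))
  d[pos] <- stats::runif(k, lo, hi)
  d
}

# Low-rate test profile with gentle noise.
quick_profile <- function(...) {
  sim_profile(name = "test", p_bh = 0.03, p_cl = 0.015, noise_sd = 0.02, ...)
}

# Match detected apneic cycles to ground-truth apneic cycles by onset
# proximity; returns indices into the truth apneic set (NA when unmatched).
match_onsets <- function(detected, truth, tol = 0.3) {
  vapply(detected, function(t0) {
    j <- which.min(abs(truth - t0))
    if (length(j) && abs(truth[j] - t0) <= tol) j else NA_integer_
  }, integer(1))
}
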