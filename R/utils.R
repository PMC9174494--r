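`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' simulation helpers do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic derived seed (kept below 2^31 - 1); used to decouple the audio
# synthesis stream from the pressure/ground-truth stream.
derive_seed <- function(seed, stream = 1L) {
  as.integer((as.numeric(seed) * 48271 + 1013904223 * as.numeric(stream)) %%
               2147483647)
}

# Running quantile of a signal, computed on a coarse time grid and linearly
# interpolated back to sample resolution.  A low quantile over a window longer
# than the longest apneic plateau tracks the end-expiratory baseline without
# being dragged up by breath-hold plateaus.
running_quantile <- function(x, fs, window = 5, prob = 0.1, step = 0.25) {
  n <- length(x)
  half <- window / 2
  grid <- seq(0, (n - 1) / fs, by = step)
  sub <- max(1L, floor(fs / 250))
  vals <- vapply(grid, function(t0) {
    i0 <- max(1L, round((t0 - half) * fs))
    i1 <- min(n, round((t0 + half) * fs))
    stats::quantile(x[seq(i0, i1, by = sub)], prob, names = FALSE, type = 5)
  }, numeric(1))
  if (length(grid) < 2) return(rep(vals[1], n))
  if (length(vals) >= 5) {            # smooth grid-level jitter
    sm <- stats::filter(vals, rep(1 / 3, 3))
    vals[!is.na(sm)] <- sm[!is.na(sm)]
  }
  stats::approx(grid, vals, xout = (seq_len(n) - 1) / fs, rule = 2)$y
}

# Running amplitude scale (per-sample), from high quantiles of the
# baseline-subtracted trace over coarse blocks.
running_amplitude <- function(d, fs, window = 10, step = 5) {
  n <- length(d)
  grid <- seq(0, (n - 1) / fs, by = step)
  half <- window / 2
  sub <- max(1L, floor(fs / 250))
  vals <- vapply(grid, function(t0) {
    i0 <- max(1L, round((t0 - half) * fs))
    i1 <- min(n, round((t0 + half) * fs))
    stats::quantile(d[seq(i0, i1, by = sub)], 0.99, names = FALSE, type = 5)
  }, numeric(1))
  vals <- pmax(vals, 1e-12)
  if (length(grid) < 2) return(rep(vals[1], n))
  stats::approx(grid, vals, xout = (seq_len(n) - 1) / fs, rule = 2)$y
}

# Raised-cosine bump of unit height centred at t0 (seconds), width w.
# Returns the additive waveform evaluated at sample times tt.
rc_bump <- function(tt, t0, w) {
  u <- (tt - t0) / w
  out <- numeric(length(tt))
  in_w <- abs(u) < 0.5
  out[in_w] <- 0.5 * (1 + cos(2 * pi * u[in_w]))
  out
}
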