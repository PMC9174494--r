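#' Pressure and audio trace containers
#'
#' A `pressure_trace` holds chamber-pressure samples (inspiration upward) with
#' their sample rate, optional synchronization marks (trigger pulse and chamber
#' knock, seconds from trace start on the pressure clock), an optional
#' volume-calibration scale (µL per raw unit), and free-form metadata (pup id,
#' genotype, age, weight).  An `audio_trace` holds the microphone samples and
#' their rate on the audio clock.
#'
#' @param samples numeric vector of samples.
#' @param sample_rate sampling rate (Hz).
#' @param trigger_time,knock_time synchronization mark times (s) or `NULL`.
#' @param volume_scale µL per raw unit, or `NULL` if uncalibrated.
#' @param metadata named list.
#' @return an object of class `pressure_trace` / `audio_trace`.
#' @export
pressure_trace <- function(samples, sample_rate, trigger_time = NULL,
                           knock_time = NULL, volume_scale = NULL,
                           metadata = list()) {
  stopifnot(sample_rate > 0, all(is.finite(samples)))
  dur <- length(samples) / sample_rate
  for (tm in c(trigger_time, knock_time)) {
    if (!is.null(tm) && (tm < 0 || tm > dur)) {
      stop("sync mark outside the recording", call. = FALSE)
    }
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 trigger_time = trigger_time, knock_time = knock_time,
                 volume_scale = volume_scale, metadata = metadata),
            class = "pressure_trace")
}

#' @rdname pressure_trace
#' @export
audio_trace <- function(samples, sample_rate) {
  stopifnot(sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("Pressure trace: %.1f s at %g Hz%s\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              if (is.null(x$volume_scale)) " (uncalibrated)"
              else sprintf(", %.3g uL/unit", x$volume_scale)))
  invisible(x)
}

#' @export
print.audio_trace <- function(x, ...) {
  cat(sprintf("Audio trace: %.1f s at %g Hz\n",
              length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

cycle_series <- function(df, total_duration, sample_rate) {
  stopifnot(all(df$ti > 0), all(df$te > 0))
  structure(df, total_duration = total_duration, sample_rate = sample_rate,
            class = c("cycle_series", "data.frame"))
}

empty_cycle_series <- function(total_duration, sample_rate) {
  df <- data.frame(onset = numeric(0), ti = numeric(0), te = numeric(0),
                   duration = numeric(0), amplitude = numeric(0),
                   end_exp = numeric(0), artifact = logical(0))
  structure(df, total_duration = total_duration, sample_rate = sample_rate,
            class = c("cycle_series", "data.frame"))
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf("Cycle series: %d cycles over %.1f s (median duration %.3f s)\n",
              nrow(x), attr(x, "total_duration"),
              if (nrow(x)) stats::median(x$duration) else NA_real_))
  invisible(x)
}

# Replace a window around a sync mark by linear interpolation so the large
# trigger/knock transients do not masquerade as breaths.
mask_mark <- function(x, fs, t0, before = 0.02, after = 0.06) {
  if (is.null(t0)) return(x)
  i0 <- max(2L, round((t0 - before) * fs))
  i1 <- min(length(x) - 1L, round((t0 + after) * fs))
  if (i1 <= i0) return(x)
  x[i0:i1] <- seq(x[i0 - 1L], x[i1 + 1L], length.out = i1 - i0 + 1L)
  x
}

#' Segment a pressure trace into respiratory cycles
#'
#' Inspiration onsets are detected on the low-pass-filtered,
#' baseline-subtracted trace with a two-level hysteresis: a cycle starts at the
#' upward crossing of the arming level provided the trace has returned below it
#' since the previous onset and subsequently crosses the firing level.  Both
#' levels scale with the running tidal amplitude.  The baseline is a running
#' low quantile, which tracks the end-expiratory level without being dragged
#' up by breath-hold plateaus; apneic pauses and plateau-riding resuming
#' efforts are therefore absorbed into the enclosing cycle's expiratory phase,
#' so cycle durations reflect the cycle-to-cycle values used on Poincaré
#' plots.  Within a cycle, Ti runs from onset to the inspiratory peak and Te
#' from the peak to the next onset.
#'
#' @param trace a [pressure_trace()]; at least 2 s of signal.
#' @param lowpass_hz low-pass corner for onset detection (Hz).
#' @param baseline_window,baseline_prob window (s) and quantile of the running
#'   baseline estimator.
#' @param fire_frac,arm_frac firing and arming thresholds as fractions of the
#'   running tidal amplitude.
#' @param min_cycle refractory period between onsets (s).
#' @param artifact_mult cycles whose amplitude exceeds this multiple of the
#'   median amplitude are flagged as movement artifacts.
#' @return a `cycle_series` data frame (onset, ti, te, duration, amplitude,
#'   end_exp, artifact) with attribute `total_duration`.  Amplitudes are in µL
#'   when the trace is calibrated, raw units otherwise.  A flat trace yields an
#'   empty series with a warning.
#' @export
segment_breaths <- function(trace, lowpass_hz = 20, baseline_window = 5,
                            baseline_prob = 0.1, fire_frac = 0.15,
                            arm_frac = 0.05, min_cycle = 0.1,
                            artifact_mult = 5) {
  fs <- trace$sample_rate
  x <- trace$samples
  if (length(x) < 2 * fs) stop("need at least 2 s of signal", call. = FALSE)
  total_dur <- length(x) / fs
  if (diff(range(x)) == 0) {
    warning("flat trace: no respiratory cycles detected")
    return(empty_cycle_series(total_dur, fs))
  }
  x <- mask_mark(x, fs, trace$trigger_time, 0.02, 0.04)
  x <- mask_mark(x, fs, trace$knock_time, 0.02, 0.06)

  bf <- signal::butter(4, lowpass_hz / (fs / 2))
  xf <- signal::filtfilt(bf, x)
  base <- running_quantile(xf, fs, baseline_window, baseline_prob)
  d <- xf - base
  vt <- running_amplitude(d, fs)

  onsets <- detect_onsets(d, fire_frac * vt, arm_frac * vt, fs, min_cycle)
  if (length(onsets) < 2) {
    warning("fewer than two inspiration onsets detected")
    return(empty_cycle_series(total_dur, fs))
  }

  scale <- trace$volume_scale %||% 1
  m <- length(onsets) - 1L
  oi <- floor(onsets)                     # integer part, for indexing
  onset_t <- ti <- te <- amp <- eel <- numeric(m)
  for (i in seq_len(m)) {
    i0 <- oi[i]; i1 <- oi[i + 1L]
    pk <- i0 - 1L + which.max(d[i0:(i1 - 1L)])
    if (pk <= i0) pk <- i0 + 1L
    onset_t[i] <- (onsets[i] - 1) / fs
    ti[i] <- (pk - onsets[i]) / fs
    te[i] <- (onsets[i + 1L] - pk) / fs
    amp[i] <- (d[pk] - d[i0]) * scale
    eel[i] <- d[i1 - 1L] * scale
  }
  artifact <- amp > artifact_mult * stats::median(amp)
  cycle_series(data.frame(onset = onset_t, ti = ti, te = te,
                          duration = ti + te, amplitude = amp, end_exp = eel,
                          artifact = artifact),
               total_duration = total_dur, sample_rate = fs)
}

# Hysteresis onset detector on the baseline-subtracted signal.  Returns
# fractional sample positions: the sub-sample crossing of the arming level,
# interpolated linearly, so cycle durations are not quantized to the sample
# grid.
detect_onsets <- function(d, fire, arm, fs, min_cycle) {
  below <- which(d < arm)
  if (!length(below)) return(numeric(0))
  above_fire <- d > fire
  fire_idx <- which(diff(above_fire) == 1L) + 1L
  if (!length(fire_idx)) return(numeric(0))
  pos <- findInterval(fire_idx, below)
  onsets <- numeric(0)
  last_onset <- -Inf
  refr <- min_cycle * fs
  for (j in seq_along(fire_idx)) {
    if (pos[j] == 0L) next
    b <- below[pos[j]]
    if (b <= last_onset) next          # not re-armed since previous onset
    if (b + 1L - last_onset < refr) next
    num <- arm[b] - d[b]
    den <- (d[b + 1L] - d[b]) - (arm[b + 1L] - arm[b])
    frac <- if (is.finite(den) && den > 0) min(1, max(0, num / den)) else 0
    onsets <- c(onsets, b + frac)
    last_onset <- b + 1L
  }
  onsets
}

#' Calibrate the volume scale of a pressure trace
#'
#' The chamber is calibrated by injecting a known air volume (2.5 µL with a
#' Hamilton syringe in the reference protocol), which produces a step in the
#' pressure trace.  The scale is `injected_volume / mean step amplitude`
#' across the stated injection times; it is stored on the trace so that
#' subsequent segmentation reports amplitudes in µL.
#'
#' @param trace a [pressure_trace()].
#' @param injection_times times (s) of the injections; at least one.
#' @param injected_volume injected volume (µL), default 2.5.
#' @return the trace with `volume_scale` set.  The scale is
#'   `trace$volume_scale`.
#' @export
calibrate_volume <- function(trace, injection_times, injected_volume = 2.5) {
  stopifnot(length(injection_times) >= 1)
  fs <- trace$sample_rate
  x <- trace$samples
  steps <- vapply(injection_times, function(t0) {
    pre <- x[max(1L, round((t0 - 0.4) * fs)):round((t0 - 0.05) * fs)]
    post <- x[round((t0 + 0.05) * fs):min(length(x), round((t0 + 0.4) * fs))]
    step <- mean(post) - mean(pre)
    noise <- stats::sd(diff(pre)) / sqrt(2)
    if (!is.finite(step) || step <= 0 || step < 5 * noise / sqrt(length(pre))) {
      stop(sprintf("no detectable injection step at t = %.3f s", t0),
           call. = FALSE)
    }
    step
  }, numeric(1))
  trace$volume_scale <- injected_volume / mean(steps)
  trace
}

#' Ventilation summary of a cycle series
#'
#' Per-cycle breathing frequency is `F_R = 60 / (Ti + Te)` (breaths/min); the
#' summary reports its mean together with the mean tidal volume `V_T` (µL) and
#' the minute ventilation `V_E = F_R * V_T / 1000`.  When a body weight is
#' supplied the weight-normalized `V_E / weight` (µL/g/min scale) is reported
#' as well; both forms are exposed because conventions differ.
#'
#' @param series a `cycle_series` from [segment_breaths()]; non-empty.
#' @param weight_g pup mass (g), optional.
#' @return list with `f_r`, `v_t`, `v_e`, `v_e_per_g` (NA without weight) and
#'   `n_cycles`.
#' @export
ventilation_summary <- function(series, weight_g = NULL) {
  keep <- !series$artifact
  if (!nrow(series) || !any(keep)) stop("empty cycle series", call. = FALSE)
  fr <- mean(60 / series$duration[keep])
  vt <- mean(series$amplitude[keep])
  ve <- fr * vt / 1000
  structure(list(f_r = fr, v_t = vt, v_e = ve,
                 v_e_per_g = if (is.null(weight_g)) NA_real_ else ve / weight_g,
                 n_cycles = sum(keep)),
            class = "ventilation_summary")
}

#' @export
print.ventilation_summary <- function(x, ...) {
  cat(sprintf("F_R %.1f breaths/min, V_T %.2f uL, V_E %.3f (per g: %.3f)\n",
              x$f_r, x$v_t, x$v_e, x$v_e_per_g))
  invisible(x)
}
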