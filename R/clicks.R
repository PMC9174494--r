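# Click detection in ultrasound audio, two-point clock synchronization, and
# peri-event alignment statistics.
#
# A click is a sub-millisecond broad-band transient associated with the
# re-opening of closed airway cavities; it is time-locked to small upward
# pressure shifts that terminate breath holds and to lung-compression events
# during vocal breathing.

#' Detect clicks in an audio trace
#'
#' Candidate events are short-time energy excursions of the high-pass-filtered
#' signal above `median + k * MAD`; events longer than `max_duration` (e.g.
#' knocks, vocal syllables) are rejected, duplicates within the refractory
#' period are merged, and tonal events are rejected by a spectral-flatness
#' threshold (clicks are broad-band, ultrasonic vocalizations are nearly pure
#' tones).
#'
#' @param audio an [audio_trace()]; sample rate at least 20 kHz.
#' @param highpass_hz high-pass corner (Hz).
#' @param k detection threshold in MADs above the median envelope.
#' @param max_duration maximal click duration (s).
#' @param refractory merge window (s) for duplicate detections.
#' @param flatness_threshold minimal spectral flatness (geometric/arithmetic
#'   mean of the power spectrum above the high-pass corner).
#' @param rms_window short-time RMS window (s).
#' @return data frame with one row per click: `time` (s, audio clock),
#'   `duration` (s), `energy_db` (peak envelope over the median noise floor).
#'   Empty for silent audio.
#' @export
detect_clicks <- function(audio, highpass_hz = 5000, k = 8,
                          max_duration = 0.002, refractory = 0.01,
                          flatness_threshold = 0.4, rms_window = 2e-4) {
  fs <- audio$sample_rate
  if (fs < 20000) stop("audio sample rate must be >= 20 kHz", call. = FALSE)
  x <- audio$samples
  empty <- data.frame(time = numeric(0), duration = numeric(0),
                      energy_db = numeric(0))
  if (length(x) < fs %/% 100 || all(x == 0)) return(empty)

  y <- fft_highpass(x, fs, highpass_hz)
  w <- max(4L, round(rms_window * fs))
  cs <- cumsum(c(0, y^2))
  env <- sqrt((cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w)
  sub <- env[seq(1, length(env), by = max(1L, length(env) %/% 2e6))]
  med <- stats::median(sub)
  thr <- med + k * stats::mad(sub)
  if (!is.finite(thr) || thr <= 0) return(empty)

  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(runs)) return(empty)
  # merge runs separated by less than the refractory period
  gap <- runs$start[-1] - runs$end[-nrow(runs)]
  grp <- cumsum(c(1L, as.integer(gap > refractory * fs)))
  merged <- data.frame(
    start = tapply(runs$start, grp, min),
    end = tapply(runs$end, grp, max)
  )

  rows <- lapply(seq_len(nrow(merged)), function(i) {
    i0 <- merged$start[i]; i1 <- merged$end[i]
    dur <- (i1 - i0 + 1L) / fs
    if (dur >= max_duration) return(NULL)
    pk <- i0 - 1L + which.max(env[i0:i1])
    t_peak <- (pk - 1L + w / 2) / fs         # centre of the RMS window
    if (event_flatness(y, fs, t_peak, highpass_hz) < flatness_threshold) {
      return(NULL)
    }
    data.frame(time = t_peak, duration = dur,
               energy_db = 20 * log10(max(env[pk], .Machine$double.eps) / med))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

# Zero-phase high-pass via the frequency domain: a raised-cosine transition
# from zero below 0.8 * cutoff to one at the cutoff.  Long traces are
# processed by overlap-save on power-of-two blocks; the margin (82 ms at
# 50 kHz) dwarfs the effective impulse response of the ~1 kHz-wide
# transition, so block seams are numerically invisible.
fft_highpass <- function(x, fs, cutoff, block = 2^20, margin = 4096) {
  n <- length(x)
  m <- min(stats::nextn(n), block)
  # frequency response for block size m
  fr <- (seq_len(m) - 1) / m * fs
  fr <- pmin(fr, fs - fr)              # fold to physical frequency
  h <- numeric(m)
  lo <- 0.8 * cutoff
  h[fr >= cutoff] <- 1
  tr <- fr > lo & fr < cutoff
  h[tr] <- 0.5 * (1 - cos(pi * (fr[tr] - lo) / (cutoff - lo)))

  if (n <= m - 2 * margin || n <= m) {
    y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) * h,
                       inverse = TRUE)) / m
    return(y[seq_len(n)])
  }
  step <- m - 2L * margin
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j0 <- i - margin
    j1 <- j0 + m - 1L
    seg <- numeric(m)
    src0 <- max(1L, j0); src1 <- min(n, j1)
    seg[(src0 - j0 + 1L):(src1 - j0 + 1L)] <- x[src0:src1]
    y <- Re(stats::fft(stats::fft(seg) * h, inverse = TRUE)) / m
    take <- min(step, n - i + 1L)
    out[i:(i + take - 1L)] <- y[(margin + 1L):(margin + take)]
    i <- i + step
  }
  out
}

# Flatness of a candidate event: maximum spectral flatness over short
# overlapping frames around the event peak, so a sub-millisecond broad-band
# transient is judged within its own extent rather than diluted by the
# surrounding noise floor; a tonal event scores low in every frame.
event_flatness <- function(y, fs, t_peak, lo_hz, frame = 6e-4, n_frames = 5) {
  half <- round(frame * fs / 2)
  step <- round(frame * fs / 2)
  centres <- round(t_peak * fs) + step * (seq_len(n_frames) - (n_frames + 1) / 2)
  vals <- vapply(centres, function(cc) {
    i0 <- max(1L, cc - half); i1 <- min(length(y), cc + half)
    spectral_flatness(y[i0:i1], fs, lo_hz)
  }, numeric(1))
  max(vals)
}

# Spectral flatness (Wiener entropy) of the power spectrum restricted to the
# band above `lo_hz`: ~1 for broad-band noise, ~0 for a pure tone.
spectral_flatness <- function(seg, fs, lo_hz) {
  m <- length(seg)
  if (m < 16) return(0)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
  pw <- Mod(stats::fft(seg * win))^2
  freqs <- (seq_len(m) - 1) * fs / m
  band <- freqs >= lo_hz & freqs <= fs / 2
  p <- pw[band] + .Machine$double.eps
  exp(mean(log(p))) / mean(p)
}

#' Detect the trigger and knock synchronization marks
#'
#' The trigger is the 10 ms pulse near the start of the recording; the knock
#' is the largest impulse in the final tenth.  Both are located as the peak of
#' a matched moving-average of the squared signal, so the detected time is the
#' centre of the mark in either channel.
#'
#' @param x numeric samples (pressure or audio).
#' @param fs sample rate (Hz).
#' @return named numeric `c(trigger, knock)` in seconds on the channel's own
#'   clock.
#' @export
detect_sync_marks <- function(x, fs) {
  n <- length(x)
  ma_peak <- function(i0, i1, w) {
    seg <- x[i0:i1]^2
    ww <- max(2L, round(w * fs))
    cs <- cumsum(c(0, seg))
    m <- (cs[(ww + 1):length(cs)] - cs[1:(length(cs) - ww)]) / ww
    (i0 - 1L + which.max(m) - 1L + ww / 2) / fs
  }
  trig <- ma_peak(1L, max(round(0.1 * n), round(2 * fs)), 0.01)
  knock <- ma_peak(round(0.9 * n), n, 0.004)
  c(trigger = trig, knock = knock)
}

#' Fit the two-point audio-to-pressure clock map
#'
#' With the trigger near the start and the knock near the end detected in both
#' channels, the audio clock is modelled as
#' `t_audio = offset + (1 + drift) * t_pressure`; the drift follows from the
#' ratio of the mark separations and the offset from the trigger pair.  The
#' residual reports the irreducible mark-quantization jitter when the sample
#' rates are supplied.
#'
#' @param pressure_marks numeric `c(trigger, knock)` (s, pressure clock).
#' @param audio_marks numeric `c(trigger, knock)` (s, audio clock).
#' @param pressure_rate,audio_rate optional sample rates (Hz) used for the
#'   residual estimate.
#' @return a `sync_model`: `offset` (s), `drift_ppm`, `residual` (s), `scale`.
#' @export
fit_sync <- function(pressure_marks, audio_marks, pressure_rate = NULL,
                     audio_rate = NULL) {
  if (length(pressure_marks) != 2 || any(!is.finite(pressure_marks))) {
    stop("missing synchronization mark in the pressure channel", call. = FALSE)
  }
  if (length(audio_marks) != 2 || any(!is.finite(audio_marks))) {
    stop("missing synchronization mark in the audio channel", call. = FALSE)
  }
  b <- (audio_marks[2] - audio_marks[1]) / (pressure_marks[2] - pressure_marks[1])
  offset <- audio_marks[1] - b * pressure_marks[1]
  drift_ppm <- (b - 1) * 1e6
  if (abs(drift_ppm) > 200) {
    stop(sprintf("implausible clock drift (%.0f ppm); check mark detection",
                 drift_ppm), call. = FALSE)
  }
  residual <- 0
  if (!is.null(pressure_rate) && !is.null(audio_rate)) {
    residual <- 0.5 / pressure_rate + 0.5 / audio_rate
  }
  structure(list(offset = unname(offset), drift_ppm = unname(drift_ppm),
                 residual = residual, scale = unname(b)),
            class = "sync_model")
}

#' @export
print.sync_model <- function(x, ...) {
  cat(sprintf("Sync model: offset %.4f ms, drift %.2f ppm\n",
              1000 * x$offset, x$drift_ppm))
  invisible(x)
}

#' Map audio-clock times onto the pressure clock
#'
#' @param sync a `sync_model` from [fit_sync()].
#' @param times audio-clock times (s).
#' @return pressure-clock times (s).
#' @export
apply_sync <- function(sync, times) {
  (times - sync$offset) / sync$scale
}

#' Peri-event histogram of click times
#'
#' For each event, offsets of clicks falling inside the centred window are
#' collected and binned; the central bin spans `[-bin/2, +bin/2)` (half-open,
#' ties to the earlier bin).  The mode-bin fraction is the fraction of events
#' whose nearest click lies in the central bin — the alignment statistic used
#' to show that clicks are time-locked to respiratory events.
#'
#' @param clicks click times (s, pressure clock).
#' @param event_times alignment events (s); non-empty.
#' @param window full window width (s); default 1 s (use 2 s for breath-hold
#'   alignment).
#' @param bin bin width (s), default 20 ms.
#' @return list with `counts` (named by bin centre), `bin_centers`,
#'   `mode_fraction`, `n_events`, `n_clicks_in_window`.
#' @export
peri_event_histogram <- function(clicks, event_times, window = 1, bin = 0.02) {
  if (!length(event_times)) stop("empty event list", call. = FALSE)
  kk <- round(window / (2 * bin))
  if (kk < 1) stop("bin must divide the window", call. = FALSE)
  edges <- (seq(-kk, kk + 1) - 0.5) * bin
  centers <- (seq(-kk, kk)) * bin
  counts <- integer(length(centers))
  central_hit <- logical(length(event_times))
  for (i in seq_along(event_times)) {
    off <- clicks - event_times[i]
    off <- off[off >= edges[1] & off < edges[length(edges)]]
    if (length(off)) {
      ix <- findInterval(off, edges)
      counts <- counts + tabulate(ix, nbins = length(centers))
      nearest <- off[which.min(abs(off))]
      central_hit[i] <- nearest >= -bin / 2 && nearest < bin / 2
    }
  }
  names(counts) <- sprintf("%.3f", centers)
  list(counts = counts, bin_centers = centers,
       mode_fraction = mean(central_hit),
       n_events = length(event_times),
       n_clicks_in_window = sum(counts))
}

#' Fraction of clicks per respiratory context
#'
#' Each click is assigned to exactly one labelled context interval (vocal
#' breathing, breath-holding apnea, eupnea, central-like apnea) by its
#' corrected time; fractions are over the assigned clicks and sum to one when
#' any click is assigned.
#'
#' @param clicks click times (s, pressure clock).
#' @param contexts data frame with columns `start`, `end`, `label`;
#'   non-overlapping intervals.
#' @return named fractions over all labels present in `contexts`, with
#'   attributes `n_assigned` and `flagged` (TRUE when no click could be
#'   assigned, in which case the fractions are NA).
#' @export
click_context_fractions <- function(clicks, contexts) {
  stopifnot(all(c("start", "end", "label") %in% names(contexts)))
  o <- order(contexts$start)
  contexts <- contexts[o, ]
  if (nrow(contexts) > 1 &&
      any(contexts$start[-1] < contexts$end[-nrow(contexts)] - 1e-9)) {
    stop("overlapping context intervals", call. = FALSE)
  }
  labels <- unique(contexts$label)
  idx <- findInterval(clicks, contexts$start)
  ok <- idx >= 1 & clicks < contexts$end[pmax(idx, 1L)]
  assigned <- contexts$label[idx[ok]]
  n <- length(assigned)
  fr <- if (n) {
    tab <- table(factor(assigned, levels = labels))
    as.numeric(tab) / n
  } else rep(NA_real_, length(labels))
  names(fr) <- labels
  attr(fr, "n_assigned") <- n
  attr(fr, "flagged") <- n == 0
  fr
}

#' Context intervals from simulation ground truth
#'
#' Maps ground-truth cycle kinds onto the click-context labels (regular ->
#' eupnea, central_like -> central) and merges adjacent cycles of equal
#' context into single intervals.
#'
#' @param truth a `ground_truth` from [simulate_recording()].
#' @return data frame `start`, `end`, `label` suitable for
#'   [click_context_fractions()].
#' @export
context_intervals <- function(truth) {
  cyc <- truth$cycles
  lab <- c(regular = "eupnea", vocal = "vocal", breath_hold = "breath_hold",
           central_like = "central")[cyc$kind]
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = cyc$onset[starts],
             end = cyc$onset[ends] + cyc$duration[ends],
             label = r$values, stringsAsFactors = FALSE)
}
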