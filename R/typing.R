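# Classification of apneic cycles into breath-holding (post-inspiratory
# retention of air: pressure plateau above the end-expiratory baseline, often
# terminated by a click and an abrupt deflation) versus central-like (pause at
# baseline after a normal breath, lung deflated).

#' Classify apneic cycles as breath-holding or central-like
#'
#' For each apneic cycle the retained-volume plateau is measured as the median
#' trace level during the pause, relative to the local end-expiratory
#' baseline, in units of the tidal amplitude.  The decision rule is:
#' breath-hold if `plateau >= plateau_threshold`, or if a click falls within
#' `click_window` of the pause-terminating deflation and
#' `plateau >= deflated_threshold`; central-like if
#' `plateau < deflated_threshold`; intermediate cases are flagged ambiguous
#' and resolved to central-like (the conservative tie-break).  Resuming
#' inspiratory efforts are reported when at least two sub-threshold upward
#' deflections of increasing amplitude ride the plateau.
#'
#' @param trace the [pressure_trace()] the series was segmented from.
#' @param series the `cycle_series`.
#' @param corc a `corc_estimate` (or threshold in s) defining apneic cycles.
#' @param clicks optional click times (s, pressure clock after sync), e.g.
#'   from [detect_clicks()] + [apply_sync()].
#' @param plateau_threshold plateau level (V_T units) above which the cycle is
#'   a breath hold outright.
#' @param deflated_threshold plateau level below which the lung is considered
#'   deflated (central-like).
#' @param click_window click-association half-window (s) around the terminal
#'   deflation.
#' @return data frame of apnea events, one row per apneic cycle: `cycle`,
#'   `onset`, `duration`, `type`, `plateau_level`, `has_resuming_efforts`,
#'   `click_time` (NA if none), `ambiguous`.
#' @export
classify_apneas <- function(trace, series, corc, clicks = NULL,
                            plateau_threshold = 0.3, deflated_threshold = 0.1,
                            click_window = 0.1) {
  labels <- label_cycles(series, corc)
  idx <- which(labels == "apneic")
  out <- data.frame(cycle = integer(0), onset = numeric(0),
                    duration = numeric(0), type = character(0),
                    plateau_level = numeric(0),
                    has_resuming_efforts = logical(0),
                    click_time = numeric(0), ambiguous = logical(0),
                    stringsAsFactors = FALSE)
  if (!length(idx)) return(out)

  fs <- trace$sample_rate
  x <- mask_mark(trace$samples, fs, trace$trigger_time, 0.02, 0.04)
  x <- mask_mark(x, fs, trace$knock_time, 0.02, 0.06)
  bf <- signal::butter(4, 20 / (fs / 2))
  scale <- trace$volume_scale %||% 1
  d <- signal::filtfilt(bf, x) * scale
  vt <- stats::median(series$amplitude[labels == "repetitive"])
  med_reg <- stats::median(series$duration[labels == "repetitive"])

  rows <- lapply(idx, function(i) {
    classify_one(d, fs, series$onset[i], series$duration[i], vt, med_reg,
                 clicks, plateau_threshold, deflated_threshold, click_window,
                 cycle = i)
  })
  do.call(rbind, rows)
}

#' @rdname classify_apneas
#' @param apneic_index index (row) of one apneic cycle in `series`.
#' @export
classify_apnea <- function(trace, series, apneic_index, corc, clicks = NULL,
                           plateau_threshold = 0.3, deflated_threshold = 0.1,
                           click_window = 0.1) {
  labels <- label_cycles(series, corc)
  if (apneic_index < 1 || apneic_index > nrow(series)) {
    stop("apneic_index out of range", call. = FALSE)
  }
  if (labels[apneic_index] != "apneic") {
    stop("cycle is not labelled apneic", call. = FALSE)
  }
  ev <- classify_apneas(trace, series, corc, clicks, plateau_threshold,
                        deflated_threshold, click_window)
  ev[ev$cycle == apneic_index, , drop = FALSE]
}

classify_one <- function(d, fs, onset, duration, vt, med_reg, clicks,
                         plateau_threshold, deflated_threshold, click_window,
                         cycle) {
  t_end <- onset + duration
  guard <- min(1.5 * med_reg, 0.4 * duration)
  p0 <- round((onset + guard) * fs) + 1L
  p1 <- round((t_end - 0.15) * fs)
  if (p1 - p0 < 0.05 * fs) {            # degenerate: use the middle half
    p0 <- round((onset + 0.25 * duration) * fs) + 1L
    p1 <- round((onset + 0.75 * duration) * fs)
  }
  p0 <- max(1L, p0); p1 <- min(length(d), p1)
  pause <- d[p0:p1]
  # end-expiratory reference from the 2 s of (regular) breathing preceding
  # the apneic cycle: unbiased even when the pause dominates any centred
  # baseline window
  r0 <- max(1L, round((onset - 2) * fs)); r1 <- max(r0 + 1L, round(onset * fs))
  ref <- stats::quantile(d[r0:r1], 0.1, names = FALSE, type = 5)
  plateau <- (stats::median(pause) - ref) / vt

  # terminal deflation: steepest fall in the last quarter second of the
  # cycle (kept clear of resuming-effort flanks earlier in the plateau)
  q0 <- max(1L, round((t_end - 0.25) * fs))
  q1 <- min(length(d) - 1L, round(t_end * fs))
  slope <- diff(d[q0:q1])
  t_defl <- (q0 - 1L + which.min(slope)) / fs

  click_time <- NA_real_
  if (!is.null(clicks) && length(clicks)) {
    off <- abs(clicks - t_defl)
    j <- which.min(off)
    if (off[j] <= click_window) click_time <- clicks[j]
  }

  # resuming efforts: >= 2 growing upward deflections riding the plateau
  efforts <- FALSE
  if (length(pause) > fs * 0.5) {
    rel <- pause - stats::median(pause)
    pk <- local_peaks(rel, min_height = 0.1 * vt, min_spacing = 0.2 * fs)
    if (length(pk) >= 2) efforts <- rel[pk[length(pk)]] > rel[pk[1]]
  }

  ambiguous <- FALSE
  if (plateau >= plateau_threshold) {
    type <- "breath_hold"
  } else if (plateau < deflated_threshold) {
    type <- "central_like"
  } else if (!is.na(click_time)) {
    type <- "breath_hold"
  } else {
    type <- "central_like"; ambiguous <- TRUE
  }
  data.frame(cycle = cycle, onset = onset, duration = duration, type = type,
             plateau_level = plateau, has_resuming_efforts = efforts,
             click_time = click_time, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

local_peaks <- function(x, min_height, min_spacing) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > min_height]
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= min_spacing) keep <- c(keep, i)
    else if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
  }
  keep
}

#' Apneic time fraction by apnea type
#'
#' Splits the total apneic time fraction of an [apnea_summary()] into its
#' breath-holding and central-like components.  The partition is exact by
#' construction: each apneic cycle contributes its full duration to exactly
#' one type.
#'
#' @param summary an `apnea_summary`.
#' @param events the event table from [classify_apneas()] covering the same
#'   apneic cycles.
#' @return the summary with an added `by_type` named vector
#'   (`breath_hold`, `central_like`) and the events attached.
#' @export
atf_by_type <- function(summary, events) {
  if (nrow(events) != summary$n_apneas ||
      !setequal(events$cycle, summary$indices)) {
    stop("events do not cover the apneic cycles of the summary", call. = FALSE)
  }
  total <- summary$total_duration
  bh <- sum(events$duration[events$type == "breath_hold"]) / total
  cl <- sum(events$duration[events$type == "central_like"]) / total
  summary$by_type <- c(breath_hold = bh, central_like = cl)
  summary$events <- events
  summary
}
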