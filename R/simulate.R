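# Synthetic plethysmography + ultrasound audio generator.
#
# The cycle sequence is drawn first (kinds, durations, amplitudes, click
# times), then rendered to a 1 kHz pressure waveform; the audio channel is
# rendered on its own (drifted) clock from the same ground truth.

# Draw the ground-truth cycle sequence.  Assumes the RNG is already seeded.
#
# Apneic cycles are isolated ("preceded and followed by a short cycle"): after
# an apneic cycle the next draw is forced regular.  To keep the stationary
# kind fractions equal to the plain mixture probabilities (p_bh, p_cl) used by
# expected_summary(), the draw probabilities after a non-apneic cycle are
# rescaled to p / (1 - p_bh - p_cl).  Vocal bouts relabel would-be-regular
# cycles (same duration law), so they leave the apnea calibration untouched.
simulate_cycles <- function(profile, duration_s) {
  pr <- profile
  a <- pr$p_bh + pr$p_cl
  pb <- if (a > 0) pr$p_bh / (1 - a) else 0
  pc <- if (a > 0) pr$p_cl / (1 - a) else 0
  es <- expected_summary(pr)
  pv <- 0
  if (pr$vocal_rate > 0) {
    c_reg <- 60 * (1 - a) / es$mean_cycle_s   # regular cycles per minute
    avail <- c_reg - 5 * pr$vocal_rate
    if (avail <= 0) stop("vocal_rate too high for this profile", call. = FALSE)
    pv <- pr$vocal_rate / avail               # bout-start prob per free cycle
  }

  cap <- ceiling(duration_s / (0.5 * pr$mu_reg)) + 16L
  onset <- numeric(cap); dur <- numeric(cap); amp <- numeric(cap)
  kind <- character(cap); click <- rep(NA_real_, cap)
  shift <- rep(NA_real_, cap); resume <- rep(FALSE, cap)
  trunc <- rep(FALSE, cap)

  t <- 0; i <- 0L; prev_apneic <- FALSE; bout <- 0L
  while (t < duration_s) {
    i <- i + 1L
    if (prev_apneic) {
      kk <- "regular"
    } else {
      u <- stats::runif(1)
      kk <- if (u < pb) "breath_hold" else if (u < pb + pc) "central_like"
            else "regular"
    }
    if (kk == "regular") {
      if (bout > 0L) {
        kk <- "vocal"; bout <- bout - 1L
      } else if (pv > 0 && stats::runif(1) < pv) {
        kk <- "vocal"; bout <- 4L
      }
    } else {
      bout <- 0L
    }
    dd <- switch(kk,
      breath_hold  = stats::runif(1, pr$dur_bh[1], pr$dur_bh[2]),
      central_like = stats::runif(1, pr$dur_cl[1], pr$dur_cl[2]),
      max(0.1, stats::rnorm(1, pr$mu_reg, pr$sigma_reg)))
    aa <- pr$vt_mean * exp(stats::rnorm(1, 0, 0.05))
    truncated <- t + dd > duration_s
    if (truncated) dd <- duration_s - t

    cl <- NA_real_; sh <- NA_real_; rs <- FALSE
    if (kk == "breath_hold" && !truncated && dd > 0.4) {
      sh <- t + dd - 0.13                      # upward pressure shift
      if (stats::runif(1) < pr$p_click_bh) cl <- sh
      rs <- stats::runif(1) < pr$resume_prob
    } else if (kk == "vocal" && !truncated) {
      if (stats::runif(1) < pr$p_click_vocal) cl <- t + 0.75 * dd
    } else if (kk == "regular" && !truncated && pr$p_click_eupnea > 0) {
      if (stats::runif(1) < pr$p_click_eupnea) cl <- t + 0.5 * dd
    } else if (kk == "central_like" && !truncated && pr$p_click_central > 0) {
      if (stats::runif(1) < pr$p_click_central) {
        b <- min(pr$mu_reg, 0.5 * dd)
        cl <- t + b + 0.5 * (dd - b)
      }
    }

    onset[i] <- t; dur[i] <- dd; amp[i] <- aa; kind[i] <- kk
    click[i] <- cl; shift[i] <- sh; resume[i] <- rs; trunc[i] <- truncated
    prev_apneic <- kk %in% c("breath_hold", "central_like")
    t <- t + dd
  }
  data.frame(onset = onset[1:i], duration = dur[1:i], kind = kind[1:i],
             amplitude = amp[1:i], click_time = click[1:i],
             shift_time = shift[1:i], resume = resume[1:i],
             truncated = trunc[1:i], stringsAsFactors = FALSE)
}

# Render the pressure waveform (inspiration upward) at `fs` Hz.
synth_pressure <- function(cyc, profile, duration_s, fs, trigger_time,
                           knock_time) {
  n <- round(duration_s * fs)
  p <- numeric(n)
  ti_reg <- profile$ti_fraction * profile$mu_reg
  for (r in seq_len(nrow(cyc))) {
    i0 <- round(cyc$onset[r] * fs) + 1L
    i1 <- min(n, round((cyc$onset[r] + cyc$duration[r]) * fs))
    if (i1 < i0) next
    tt <- (seq(i0, i1) - i0) / fs
    dd <- cyc$duration[r]; aa <- cyc$amplitude[r]
    kk <- cyc$kind[r]
    ti <- min(ti_reg, 0.45 * dd)
    y <- if (kk == "breath_hold") {
      shape_breath_hold(tt, dd, aa, ti, profile$plateau_frac, cyc$resume[r])
    } else if (kk == "central_like") {
      shape_central(tt, dd, aa, ti, profile$mu_reg)
    } else {
      shape_regular(tt, dd, aa, ti, vocal = kk == "vocal")
    }
    p[i0:i1] <- p[i0:i1] + y
  }
  smp <- (seq_len(n) - 1) / fs
  p <- p + 5 * profile$vt_mean * rc_bump(smp, trigger_time, 0.01)
  p <- p + 12 * profile$vt_mean * rc_bump(smp, knock_time, 0.004)
  if (profile$noise_sd > 0) {
    p <- p + stats::rnorm(n, 0, profile$noise_sd * profile$vt_mean)
  }
  p
}

# Regular (and vocal) cycle: quarter-sine rise over Ti, exponential return
# over Te; vocal cycles get a faster active expiration with a small
# end-compression dip below baseline.
shape_regular <- function(tt, dd, aa, ti, vocal = FALSE) {
  te <- dd - ti
  tau <- te / if (vocal) 6 else 4
  y <- ifelse(tt < ti, aa * sin(pi / 2 * tt / ti),
              aa * exp(-(tt - ti) / tau))
  if (vocal) y <- y - 0.15 * aa * rc_bump(tt, 0.75 * dd, 0.08)
  y
}

# Breath hold: inspiration, fall to a plateau at plateau_frac * amplitude,
# optional resuming efforts of linearly growing amplitude, then a small upward
# pressure shift immediately followed by a rapid expiratory deflation.
shape_breath_hold <- function(tt, dd, aa, ti, plateau_frac, resume) {
  plat <- plateau_frac * aa
  t_drop <- ti + 0.1
  t_shift <- dd - 0.13
  t_defl <- dd - 0.09
  y <- numeric(length(tt))
  y[tt < ti] <- aa * sin(pi / 2 * tt[tt < ti] / ti)
  seg <- tt >= ti & tt < t_drop
  y[seg] <- aa + (plat - aa) * (tt[seg] - ti) / 0.1
  seg <- tt >= t_drop & tt < t_defl
  y[seg] <- plat
  seg <- tt >= t_defl
  y[seg] <- plat * exp(-(tt[seg] - t_defl) / 0.02)
  if (resume) {
    span0 <- t_drop + 0.25
    span1 <- t_shift - 0.25
    if (span1 - span0 > 0.5) {
      centers <- seq(span0, span1, by = 0.4)
      k <- length(centers)
      if (k >= 2) {
        heights <- seq(0.2, 1.0, length.out = k) * aa
        for (j in seq_len(k)) {
          y <- y + heights[j] * rc_bump(tt, centers[j], 0.15)
        }
      }
    }
  }
  y + 0.15 * aa * rc_bump(tt, t_shift, 0.05)
}

# Central-like apnea: one normal breath, then a pause at baseline.
shape_central <- function(tt, dd, aa, ti, mu_reg) {
  b <- min(mu_reg, 0.5 * dd)
  y <- numeric(length(tt))
  seg <- tt < b
  y[seg] <- shape_regular(tt[seg], b, aa, min(ti, 0.45 * b))
  y
}

# Render the audio channel on its own clock: pressure-clock event times are
# mapped through t_audio = t_pressure * (1 + drift_ppm * 1e-6).
synth_audio <- function(cyc, profile, duration_s, fs_a, trigger_time,
                        knock_time) {
  f <- 1 + profile$drift_ppm * 1e-6
  n <- round(duration_s * fs_a)
  y <- stats::rnorm(n, 0, 0.01)

  # segment builders return list(i0, add); additions are applied in place in
  # this frame to avoid copying the full audio vector per event
  burst_seg <- function(t0, w, amp) {      # broadband burst, rc envelope
    i0 <- max(1L, round((t0 - w / 2) * fs_a))
    i1 <- min(n, round((t0 + w / 2) * fs_a))
    if (i1 <= i0) return(NULL)
    m <- i1 - i0 + 1L
    env <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
    list(i0 = i0, add = amp * env * stats::rnorm(m))
  }
  tone_seg <- function(t0, w, freq, amp) {
    i0 <- max(1L, round(t0 * fs_a))
    i1 <- min(n, round((t0 + w) * fs_a))
    if (i1 <= i0) return(NULL)
    m <- i1 - i0 + 1L
    env <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
    list(i0 = i0, add = amp * env * sin(2 * pi * freq * seq_len(m) / fs_a))
  }
  segs <- list()
  # trigger: band-limited 1 kHz tone burst (removed by the click detector's
  # high-pass but visible to envelope-based mark detection); mark times are
  # pulse centres in both channels
  segs[[length(segs) + 1L]] <- tone_seg(trigger_time * f - 0.005, 0.01, 1000, 0.5)
  segs[[length(segs) + 1L]] <- burst_seg(knock_time * f, 0.005, 0.8)
  for (tc in cyc$click_time[!is.na(cyc$click_time)]) {
    segs[[length(segs) + 1L]] <- burst_seg(tc * f, 0.0005, 0.3)
  }
  voc <- which(cyc$kind == "vocal" & !cyc$truncated)
  if (length(voc)) {
    freqs <- stats::runif(length(voc), 15000, 20000)
    for (j in seq_along(voc)) {
      segs[[length(segs) + 1L]] <-
        tone_seg((cyc$onset[voc[j]] + 0.25 * cyc$duration[voc[j]]) * f, 0.08,
                 freqs[j], 0.15)
    }
  }
  for (s in segs) {
    if (is.null(s)) next
    ix <- s$i0 + seq_along(s$add) - 1L
    y[ix] <- y[ix] + s$add
  }
  y
}

#' Simulate one joint plethysmography / audio recording with ground truth
#'
#' Generates a 1 kHz pressure trace (inspiration upward) and, optionally, an
#' ultrasound audio channel whose clock runs at `1 + drift_ppm * 1e-6` times
#' the pressure clock.  Both channels carry a 10 ms trigger pulse near the
#' start and a coincident knock impulse near the end for two-point clock
#' synchronization.  The returned ground truth tables every cycle (onset,
#' duration, kind), every programmed click, and the programmed apneic time
#' fractions.
#'
#' @param profile a [sim_profile()].
#' @param duration_s recording length (s), at least 10.
#' @param seed integer seed; identical inputs give bit-identical outputs.
#' @param audio generate the audio channel? (pressure and ground truth are
#'   identical either way; audio uses a derived, independent RNG stream).
#' @param audio_rate audio sample rate (Hz), default 50 kHz.
#' @return a list of class `sim_recording` with elements `pressure`
#'   (a [pressure_trace()]), `audio` (an `audio_trace` or `NULL`) and `truth`
#'   (class `ground_truth`).
#' @examples
#' rec <- simulate_recording(build_profile("control_P0_12h"), 30, seed = 1,
#'                           audio = FALSE)
#' rec$truth$atf
#' @export
simulate_recording <- function(profile, duration_s, seed, audio = TRUE,
                               audio_rate = 50000) {
  validate_sim_profile(profile)
  if (duration_s < 10) stop("duration_s must be >= 10 s (room for trigger and knock)",
                            call. = FALSE)
  trigger_time <- 0.2
  knock_time <- 0.96 * duration_s
  fs <- 1000

  res <- local_seed(seed, {
    cyc <- simulate_cycles(profile, duration_s)
    p <- synth_pressure(cyc, profile, duration_s, fs, trigger_time, knock_time)
    list(cyc = cyc, p = p)
  })
  cyc <- res$cyc

  apneic <- cyc$kind %in% c("breath_hold", "central_like")
  atf_bh <- sum(cyc$duration[cyc$kind == "breath_hold"]) / duration_s
  atf_cl <- sum(cyc$duration[cyc$kind == "central_like"]) / duration_s
  truth <- structure(list(
    cycles = cyc[, c("onset", "duration", "kind", "truncated")],
    clicks = sort(cyc$click_time[!is.na(cyc$click_time)]),
    click_context = cyc$kind[!is.na(cyc$click_time)][order(cyc$click_time[!is.na(cyc$click_time)])],
    shifts = cyc$shift_time[!is.na(cyc$shift_time)],
    trigger_time = trigger_time, knock_time = knock_time,
    duration_s = duration_s,
    atf = c(total = atf_bh + atf_cl, breath_hold = atf_bh,
            central_like = atf_cl),
    n_apneic = sum(apneic)
  ), class = "ground_truth")

  aud <- NULL
  if (audio) {
    ya <- local_seed(derive_seed(seed), {
      synth_audio(cyc, profile, duration_s, audio_rate, trigger_time,
                  knock_time)
    })
    aud <- audio_trace(ya, audio_rate)
  }

  pt <- pressure_trace(res$p, sample_rate = fs, trigger_time = trigger_time,
                       knock_time = knock_time, volume_scale = 1,
                       metadata = list(profile = profile$name,
                                       weight_g = profile$weight_g,
                                       seed = seed))
  structure(list(pressure = pt, audio = aud, truth = truth),
            class = "sim_recording")
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf("Simulated recording: %.0f s, %d cycles (%d apneic), %d clicks%s\n",
              x$truth$duration_s, nrow(x$truth$cycles), x$truth$n_apneic,
              length(x$truth$clicks),
              if (is.null(x$audio)) ", no audio" else ""))
  cat(sprintf("  programmed ATF: total %.1f%% (bh %.1f%%, cl %.1f%%)\n",
              100 * x$truth$atf["total"], 100 * x$truth$atf["breath_hold"],
              100 * x$truth$atf["central_like"]))
  invisible(x)
}

#' Simulate a cohort of pups
#'
#' Each pup gets the deterministic derived seed `seed + pup index`, so cohorts
#' are reproducible and `n_pups = 1` reproduces
#' `simulate_recording(profile, duration_s, seed + 1)`.
#'
#' @inheritParams simulate_recording
#' @param n_pups number of pups (>= 1).
#' @return list of class `sim_cohort`: `recordings` (list of `sim_recording`)
#'   and `truth` (data frame of per-pup programmed apneic time fractions).
#' @export
simulate_cohort <- function(profile, n_pups, duration_s, seed, audio = FALSE,
                            audio_rate = 50000) {
  stopifnot(n_pups >= 1)
  recs <- lapply(seq_len(n_pups), function(i) {
    simulate_recording(profile, duration_s, seed + i, audio = audio,
                       audio_rate = audio_rate)
  })
  truth <- do.call(rbind, lapply(seq_len(n_pups), function(i) {
    a <- recs[[i]]$truth$atf
    data.frame(pup = i, seed = seed + i, atf = a[["total"]],
               atf_bh = a[["breath_hold"]], atf_cl = a[["central_like"]],
               n_apneic = recs[[i]]$truth$n_apneic)
  }))
  structure(list(recordings = recs, truth = truth, profile = profile$name),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort '%s': %d pups\n", x$profile,
              nrow(x$truth)))
  cat(sprintf("  programmed ATF mean %.1f%% (bh %.1f%%, cl %.1f%%)\n",
              100 * mean(x$truth$atf), 100 * mean(x$truth$atf_bh),
              100 * mean(x$truth$atf_cl)))
  invisible(x)
}
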