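make_burst_audio <- function(times, fs = 50000, dur = 10, amp = 0.3,
                             width = 5e-4, tone = NULL) {
  y <- stats::rnorm(dur * fs, 0, 0.01)
  for (t0 in times) {
    i0 <- round((t0 - width / 2) * fs); i1 <- round((t0 + width / 2) * fs)
    m <- i1 - i0 + 1
    env <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
    y[i0:i1] <- y[i0:i1] + amp * env * stats::rnorm(m)
  }
  if (!is.null(tone)) {
    i0 <- round(tone[1] * fs); i1 <- round((tone[1] + tone[2]) * fs)
    y[i0:i1] <- y[i0:i1] + 0.2 * sin(2 * pi * tone[3] * seq_len(i1 - i0 + 1) / fs)
  }
  audio_trace(y, fs)
}

test_that("injected sub-millisecond bursts are detected at their times", {
  au <- withr::with_seed(1, make_burst_audio(c(2, 5, 8)))
  cl <- detect_clicks(au)
  expect_identical(nrow(cl), 3L)
  expect_true(all(abs(sort(cl$time) - c(2, 5, 8)) < 5e-4))
  expect_true(all(cl$duration < 0.002))
  expect_true(all(cl$energy_db > 10))
})

test_that("tonal events and silence yield no clicks", {
  au <- withr::with_seed(2, make_burst_audio(numeric(0),
                                             tone = c(4, 0.1, 17000)))
  expect_identical(nrow(detect_clicks(au)), 0L)
  expect_identical(nrow(detect_clicks(audio_trace(rep(0, 50000), 50000))), 0L)
  expect_error(detect_clicks(audio_trace(stats::rnorm(1000), 10000)),
               "20 kHz")
})

test_that("two-point sync solves offset and drift exactly", {
  sy <- fit_sync(c(0, 600), c(0, 600.030))
  expect_equal(sy$drift_ppm, 50, tolerance = 1e-9)
  expect_equal(sy$offset, 0, tolerance = 1e-12)

  id <- fit_sync(c(0.2, 288), c(0.2, 288))
  expect_equal(id$drift_ppm, 0)
  expect_equal(id$offset, 0)

  expect_error(fit_sync(c(0.2, NA), c(0.2, 288)), "pressure")
  expect_error(fit_sync(c(0.2, 288), c(0.2)), "audio")

  sy2 <- fit_sync(c(0.2, 576), c(0.3, 576.13))
  expect_equal(apply_sync(sy2, c(0.3, 576.13)), c(0.2, 576),
               tolerance = 1e-9)
})

test_that("clicks in a full joint recording are recovered and aligned", {
  pr <- build_profile("wt_joint_audio")
  rec <- simulate_recording(pr, 300, seed = 37, audio = TRUE)
  cl <- detect_clicks(rec$audio)
  am <- detect_sync_marks(rec$audio$samples, rec$audio$sample_rate)
  sy <- fit_sync(c(rec$pressure$trigger_time, rec$pressure$knock_time), am,
                 pressure_rate = 1000, audio_rate = rec$audio$sample_rate)
  expect_equal(sy$drift_ppm, pr$drift_ppm, tolerance = 0.1)  # absolute ppm
  tp <- apply_sync(sy, cl$time)
  err <- vapply(rec$truth$clicks, function(tc) min(abs(tp - tc)), numeric(1))
  fdr <- mean(vapply(tp, function(td) min(abs(rec$truth$clicks - td)),
                     numeric(1)) > 0.005)
  expect_gte(mean(err <= 0.005), 0.98)
  expect_lte(fdr, 0.02)
  expect_lt(max(err[err <= 0.005]), 0.002)   # aligned to < 2 ms
})

test_that("peri-event histograms centre, conserve and split correctly", {
  ev <- c(10, 20, 30)
  h <- peri_event_histogram(ev + 0.001, ev, window = 1, bin = 0.02)
  expect_equal(h$mode_fraction, 1)
  expect_identical(unname(h$counts[h$bin_centers == 0]), 3L)
  expect_identical(h$n_clicks_in_window, 3L)

  # uniform clicks -> no central-bin concentration, counts conserved
  clicks <- withr::with_seed(4, stats::runif(2000, 9.5, 10.5))
  hu <- peri_event_histogram(clicks, 10, window = 1, bin = 0.02)
  expect_identical(hu$n_clicks_in_window, sum(hu$counts))
  expect_lt(hu$counts[hu$bin_centers == 0] / sum(hu$counts), 0.05)

  # clicks alternating at +/-15 ms -> the two bins flanking centre
  ev2 <- seq(5, 50, by = 5)
  clicks2 <- ev2 + rep(c(-0.015, 0.015), length.out = length(ev2))
  h2 <- peri_event_histogram(clicks2, ev2, window = 1, bin = 0.02)
  expect_identical(unname(h2$counts[h2$bin_centers == 0]), 0L)
  expect_identical(sum(h2$counts[abs(h2$bin_centers - 0.02) < 1e-9 |
                                   abs(h2$bin_centers + 0.02) < 1e-9]),
                   length(ev2))
  expect_equal(h2$mode_fraction, 0)

  expect_error(peri_event_histogram(1, numeric(0)), "empty")
})

test_that("click context fractions partition the assigned clicks", {
  ctx <- data.frame(start = c(0, 10, 20, 30),
                    end = c(10, 20, 30, 40),
                    label = c("eupnea", "breath_hold", "vocal", "central"))
  fr <- click_context_fractions(c(11, 15, 19.5), ctx)
  expect_equal(as.numeric(fr), c(0, 1, 0, 0), ignore_attr = TRUE)
  expect_identical(attr(fr, "n_assigned"), 3L)

  mixed <- click_context_fractions(c(5, 12, 25, 26), ctx)
  expect_equal(sum(mixed), 1)

  none <- click_context_fractions(numeric(0), ctx)
  expect_true(all(is.na(none)))
  expect_true(attr(none, "flagged"))

  bad <- data.frame(start = c(0, 5), end = c(10, 15), label = c("a", "b"))
  expect_error(click_context_fractions(1, bad), "overlap")
})

test_that("ground-truth context intervals cover the recording", {
  pr <- build_profile("wt_joint_audio")
  rec <- simulate_recording(pr, 60, seed = 41, audio = FALSE)
  ctx <- context_intervals(rec$truth)
  expect_equal(sum(ctx$end - ctx$start), 60, tolerance = 1e-9)
  expect_true(all(ctx$label %in% c("eupnea", "vocal", "breath_hold",
                                   "central")))
})
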