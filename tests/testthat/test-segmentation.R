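test_that("noise-free regular breathing is segmented cycle for cycle", {
  pr <- sim_profile(p_bh = 0, p_cl = 0, noise_sd = 0)
  rec <- simulate_recording(pr, 60, seed = 2, audio = FALSE)
  s <- segment_breaths(rec$pressure)
  truth <- rec$truth$cycles
  # the last truth cycle has no closing onset in the detected series
  expect_lte(abs(nrow(s) - nrow(truth)), 1)
  m <- match_onsets(s$onset, truth$onset, tol = 0.1)
  expect_true(all(!is.na(m)))
  # exclude cycles touching the blanked knock window, where the waveform is
  # interpolated and durations are not constrained by the data
  clear <- abs(s$onset - rec$pressure$knock_time) > 0.7 &
    abs(s$onset + s$duration - rec$pressure$knock_time) > 0.7
  matched <- !is.na(m) & m < nrow(truth) & clear
  expect_lt(max(abs(s$duration[matched] - truth$duration[m[matched]])),
            0.0025)  # within ~2 samples at 1 kHz
})

test_that("segmentation recall and precision stay high under noise", {
  for (noise in c(0, 0.05)) {
    pr <- sim_profile(p_bh = 0.03, p_cl = 0.015, noise_sd = noise)
    rec <- simulate_recording(pr, 120, seed = 4, audio = FALSE)
    s <- segment_breaths(rec$pressure)
    truth <- rec$truth$cycles
    m <- match_onsets(s$onset, truth$onset, tol = 0.1)
    precision <- mean(!is.na(m))
    # a cycle is detectable only if its closing onset lies inside the record
    detectable <- which(truth$onset + truth$duration < 120 - 0.5)
    recall <- length(intersect(unique(m[!is.na(m)]), detectable)) /
      length(detectable)
    floor_ <- if (noise == 0) 1 else 0.98
    expect_gte(precision, floor_)
    expect_gte(recall, floor_)
  }
})

test_that("a central pause is absorbed into the enclosing cycle's Te", {
  pr <- sim_profile(p_bh = 0, p_cl = 0, noise_sd = 0)
  rec <- simulate_recording(pr, 30, seed = 2, audio = FALSE)
  x <- rec$pressure$samples
  fs <- rec$pressure$sample_rate
  # splice 2 s of baseline into a between-breath gap near 15 s
  cut <- round(15.05 * fs)
  x2 <- c(x[1:cut], rep(0, 2 * fs), x[(cut + 1):length(x)])
  tr <- pressure_trace(x2, fs, trigger_time = rec$pressure$trigger_time,
                       volume_scale = 1)
  s <- segment_breaths(tr)
  long <- s$duration[s$duration > 1]
  expect_length(long, 1)
  expect_equal(long, 2 + pr$mu_reg, tolerance = 0.15)
})

test_that("flat traces give an empty series with a warning", {
  tr <- pressure_trace(rep(0, 5000), 1000)
  expect_warning(s <- segment_breaths(tr), "flat")
  expect_identical(nrow(s), 0L)
})

test_that("volume calibration recovers the syringe scale", {
  fs <- 1000
  mk_trace <- function(steps, times, gain = 1) {
    x <- numeric(8 * fs)
    for (i in seq_along(times)) {
      x[seq(round(times[i] * fs), length(x))] <-
        x[seq(round(times[i] * fs), length(x))] + steps[i]
    }
    pressure_trace(x * gain + stats::rnorm(length(x), 0, 1e-4), fs)
  }
  tr <- withr::with_seed(1, mk_trace(0.5, 2))
  expect_equal(calibrate_volume(tr, 2, 2.5)$volume_scale, 5.0,
               tolerance = 1e-2)
  tr2 <- withr::with_seed(1, mk_trace(c(0.5, 0.52), c(2, 5)))
  expect_equal(calibrate_volume(tr2, c(2, 5), 2.5)$volume_scale, 2.5 / 0.51,
               tolerance = 1e-2)
  # scale equivariance: multiplying the raw trace by k divides the scale by k
  trk <- withr::with_seed(1, mk_trace(c(0.5, 0.52), c(2, 5), gain = 2))
  expect_equal(calibrate_volume(trk, c(2, 5), 2.5)$volume_scale,
               calibrate_volume(tr2, c(2, 5), 2.5)$volume_scale / 2,
               tolerance = 1e-2)
  # no step at the stated time
  flat <- withr::with_seed(2, pressure_trace(stats::rnorm(8000, 0, 1e-4), fs))
  expect_error(calibrate_volume(flat, 4), "no detectable")
})

test_that("ventilation summary implements F_R = 60/(Ti+Te) and V_E = F_R*V_T/1000", {
  s <- series_from_durations(rep(0.4, 10), amplitude = 8)
  v <- ventilation_summary(s, weight_g = 2)
  expect_equal(v$f_r, 150)
  expect_equal(v$v_t, 8)
  expect_equal(v$v_e, 1.2)
  expect_equal(v$v_e_per_g, 0.6)

  one <- series_from_durations(0.5, amplitude = 10)
  v1 <- ventilation_summary(one)
  expect_equal(v1$f_r, 120)
  expect_equal(v1$v_t, 10)

  expect_error(ventilation_summary(series_from_durations(numeric(0))), "empty")
})

test_that("detected cycle durations never exceed the recorded duration", {
  pr <- quick_profile()
  rec <- simulate_recording(pr, 60, seed = 8, audio = FALSE)
  s <- segment_breaths(rec$pressure)
  expect_lte(sum(s$duration), attr(s, "total_duration"))
})
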