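# Typing accuracy is evaluated against ground truth by matching detected
# apneic cycles to programmed ones by onset; programmed click times stand in
# for the audio chain (they are already on the pressure clock).

typing_accuracy <- function(noise_sd, seed = 17, duration = 300) {
  pr <- build_profile("mutant_n4A_P0_12h")
  pr$noise_sd <- noise_sd
  rec <- simulate_recording(pr, duration, seed = seed, audio = FALSE)
  s <- segment_breaths(rec$pressure)
  corc <- corc_poincare(s)
  ev <- classify_apneas(rec$pressure, s, corc, clicks = rec$truth$clicks)
  truth <- rec$truth$cycles
  ta <- truth[truth$kind %in% c("breath_hold", "central_like"), ]
  m <- match_onsets(ev$onset, ta$onset, tol = 0.3)
  ok <- !is.na(m)
  list(events = ev, truth = ta, match = m,
       accuracy = mean(ev$type[ok] ==
                         ifelse(ta$kind[m[ok]] == "breath_hold",
                                "breath_hold", "central_like")))
}

test_that("plateau and click features type apneas correctly", {
  res <- typing_accuracy(noise_sd = 0)
  expect_gte(res$accuracy, 0.95)
  # breath holds carry high plateaus, central-like apneas sit at baseline
  bh <- res$events$type == "breath_hold"
  expect_true(all(res$events$plateau_level[bh] > 0.3))
  expect_true(all(res$events$plateau_level[!bh] < 0.1))
})

test_that("typing stays accurate under measurement noise", {
  expect_gte(typing_accuracy(noise_sd = 0.05)$accuracy, 0.90)
})

test_that("clicking breath holds are typed breath_hold with the click attached", {
  res <- typing_accuracy(noise_sd = 0.03, seed = 23)
  pr <- build_profile("mutant_n4A_P0_12h")
  rec <- simulate_recording(pr, 300, seed = 23, audio = FALSE)
  clicking <- rec$truth$clicks[rec$truth$click_context == "breath_hold"]
  hits <- vapply(clicking, function(tc) {
    any(abs(res$events$click_time - tc) < 0.05 &
          res$events$type == "breath_hold", na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("an intermediate plateau without a click is ambiguous central-like", {
  pr <- sim_profile(p_bh = 0.04, p_cl = 0, plateau_frac = 0.2,
                    p_click_bh = 0, noise_sd = 0, resume_prob = 0)
  rec <- simulate_recording(pr, 200, seed = 5, audio = FALSE)
  s <- segment_breaths(rec$pressure)
  ev <- classify_apneas(rec$pressure, s, corc_poincare(s))
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$type == "central_like"))
  expect_true(all(ev$ambiguous))
  expect_true(all(ev$plateau_level > 0.1 & ev$plateau_level < 0.3))
})

test_that("ATF partitions exactly across apnea types", {
  pr <- build_profile("mutant_n4A_P0_12h")
  rec <- simulate_recording(pr, 300, seed = 29, audio = FALSE)
  s <- segment_breaths(rec$pressure)
  corc <- corc_poincare(s)
  su <- apnea_summary(s, corc)
  ev <- classify_apneas(rec$pressure, s, corc, clicks = rec$truth$clicks)
  su <- atf_by_type(su, ev)
  expect_equal(unname(su$by_type[["breath_hold"]] +
                        su$by_type[["central_like"]]), su$atf,
               tolerance = 1e-12)
})

test_that("event coverage is checked and empty summaries type to zero", {
  pr <- build_profile("mutant_n4A_P0_12h")
  rec <- simulate_recording(pr, 120, seed = 31, audio = FALSE)
  s <- segment_breaths(rec$pressure)
  corc <- corc_poincare(s)
  su <- apnea_summary(s, corc)
  ev <- classify_apneas(rec$pressure, s, corc)
  expect_error(atf_by_type(su, ev[-1, ]), "cover")

  none <- apnea_summary(s, 100)          # threshold beyond every duration
  typed <- atf_by_type(none, ev[0, ])
  expect_identical(unname(typed$by_type), c(0, 0))

  expect_error(classify_apnea(rec$pressure, s, nrow(s) + 5, corc),
               "out of range")
})
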