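test_that("poincare_points pairs consecutive durations", {
  p <- poincare_points(series_from_durations(c(0.4, 0.4, 2.5)))
  expect_equal(p$t_n, c(0.4, 0.4))
  expect_equal(p$t_n1, c(0.4, 2.5))

  const <- poincare_points(series_from_durations(rep(0.5, 20)))
  expect_true(all(const$t_n == const$t_n1))

  # one isolated long cycle -> exactly two off-diagonal pairs
  d <- c(rep(0.4, 10), 3, rep(0.4, 10))
  p2 <- poincare_points(series_from_durations(d))
  off <- abs(p2$t_n - p2$t_n1) > 0.5
  expect_identical(sum(off), 2L)

  expect_error(poincare_points(series_from_durations(0.4)), "2 cycles")
})

test_that("Poincaré CORC sits at mean + 4 SD of the repetitive cluster", {
  d <- withr::with_seed(1, stats::rnorm(500, 0.4, 0.02))
  s <- series_from_durations(d)
  est <- corc_poincare(s)
  expect_equal(est$corc, mean(d) + 4 * stats::sd(d), tolerance = 0.02)
  expect_identical(apnea_summary(s, est)$n_apneas, 0L)
})

test_that("Poincaré CORC separates a bimodal mixture", {
  for (seed in 1:5) {
    d <- withr::with_seed(seed, bimodal_durations())
    est <- corc_poincare(series_from_durations(d))
    expect_gt(est$corc, max(d[d < 1]))
    expect_lt(est$corc, min(d[d > 1]))
  }
})

test_that("CORC estimation enforces the minimum series length", {
  expect_error(corc_poincare(series_from_durations(c(0.4, 0.5))), "30 cycles")
  expect_error(corc_logthd(series_from_durations(rep(0.4, 5))), "30 cycles")
})

test_that("both CORC methods pick essentially the same apnea set", {
  for (seed in 1:10) {
    d <- withr::with_seed(seed, bimodal_durations())
    s <- series_from_durations(d)
    a <- which(label_cycles(s, corc_poincare(s)) == "apneic")
    b <- which(label_cycles(s, corc_logthd(s)) == "apneic")
    disagreement <- length(union(a, b)) - length(intersect(a, b))
    expect_lt(disagreement / max(1, length(union(a, b))), 0.05)
  }
})

test_that("ATF is non-increasing in the threshold duration", {
  for (seed in 1:5) {
    d <- withr::with_seed(seed, bimodal_durations(n = 200))
    s <- series_from_durations(d)
    grid <- withr::with_seed(seed + 100, sort(stats::runif(20, 0.2, 8)))
    atf <- vapply(grid, function(th) apnea_summary(s, th)$atf, numeric(1))
    expect_true(all(diff(atf) <= 1e-12))
  }
})

test_that("labels partition the series and the summary does the arithmetic", {
  d <- c(rep(0.4, 5), 3.0, rep(0.4, 5))
  s <- series_from_durations(d)
  lab <- label_cycles(s, 1.0)
  expect_identical(sum(lab == "apneic") + sum(lab == "repetitive"), length(d))
  expect_identical(which(lab == "apneic"), 6L)

  su <- apnea_summary(s, 1.0)
  expect_equal(su$atf, 3 / 7, tolerance = 1e-12)
  expect_identical(su$n_apneas, 1L)
  expect_false(su$consecutive)

  expect_identical(apnea_summary(s, 10)$atf, 0)

  d2 <- c(rep(0.4, 10), 3, 2.5, rep(0.4, 10))
  expect_true(apnea_summary(series_from_durations(d2), 1.0)$consecutive)
})

test_that("log-threshold CORC flags series without long cycles", {
  d <- withr::with_seed(3, stats::rnorm(100, 0.4, 0.02))
  est <- corc_logthd(series_from_durations(d))
  expect_true(est$flagged)
  expect_gt(est$corc, mean(d))
})

test_that("apnea labels recover the simulated ground truth", {
  pr <- build_profile("mutant_n4A_P0_12h")
  rec <- simulate_recording(pr, 300, seed = 13, audio = FALSE)
  s <- segment_breaths(rec$pressure)
  su <- apnea_summary(s, corc_poincare(s))
  truth <- rec$truth$cycles
  truth_apneic <- truth$onset[truth$kind %in% c("breath_hold", "central_like")]
  det_onsets <- s$onset[su$indices]
  m <- match_onsets(det_onsets, truth_apneic, tol = 0.3)
  recall <- length(unique(m[!is.na(m)])) / length(truth_apneic)
  expect_gte(recall, 0.95)
  expect_equal(su$atf, unname(rec$truth$atf["total"]), tolerance = 0.02)
})
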