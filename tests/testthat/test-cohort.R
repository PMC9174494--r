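test_that("per-pup metrics survive corrupt recordings and stay deterministic", {
  pr <- quick_profile()
  co <- simulate_cohort(pr, 3, 120, seed = 50)
  tbl <- per_pup_metrics(co$recordings)
  expect_identical(nrow(tbl), 3L)
  expect_equal(tbl$atf_bh + tbl$atf_cl, tbl$atf, tolerance = 1e-12)

  tbl2 <- per_pup_metrics(co$recordings)
  expect_identical(tbl, tbl2)

  broken <- co$recordings
  broken[[2]]$pressure$samples <- rep(0, 120000)   # flat trace
  w <- capture_warnings(tbl3 <- per_pup_metrics(broken))
  expect_true(any(grepl("failed", w)))
  expect_identical(nrow(tbl3), 2L)
  expect_length(attr(tbl3, "failures"), 1L)

  empty <- per_pup_metrics(list())
  expect_identical(nrow(empty), 0L)
})

test_that("normality gate routes to the right test", {
  g1 <- withr::with_seed(1, stats::rnorm(15))
  g2 <- withr::with_seed(2, stats::rnorm(15, 0.2))
  r <- compare_groups(g1, g2)
  expect_identical(r$test, "unpaired t")
  expect_true(r$normal)

  sk1 <- withr::with_seed(3, stats::rexp(30)^2)
  sk2 <- withr::with_seed(4, stats::rexp(30)^2)
  r2 <- compare_groups(sk1, sk2)
  expect_identical(r2$test, "Mann-Whitney")
  expect_false(r2$normal)

  r3 <- compare_groups(g1, g2, paired = TRUE)
  expect_identical(r3$test, "paired t")

  x <- withr::with_seed(5, stats::rnorm(10))
  r4 <- compare_groups(x, x, paired = TRUE)
  expect_identical(r4$statistic, 0)
  expect_equal(r4$p_value, 1)

  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("the D'Agostino-Pearson omnibus matches an independent oracle", {
  # frozen reference values from scipy.stats.normaltest on the same vectors
  r <- dagostino_pearson(sin(1:30))
  expect_equal(r$statistic, 18.607759537316372, tolerance = 1e-10)
  expect_equal(r$p.value, 9.107021380769058e-05, tolerance = 1e-10)

  r2 <- dagostino_pearson(exp(sin(1:40)))
  expect_equal(r2$statistic, 18.284663958937312, tolerance = 1e-10)
  expect_equal(r2$p.value, 1.0703742915653775e-04, tolerance = 1e-10)

  expect_error(dagostino_pearson(stats::rnorm(10)), "n >= 20")
})

test_that("the gated comparison holds its nominal level in both branches", {
  level <- function(gen, n, reps = 2000) {
    withr::with_seed(99, {
      mean(vapply(seq_len(reps), function(i) {
        compare_groups(gen(n), gen(n))$p_value < 0.05
      }, logical(1)))
    })
  }
  expect_lt(abs(level(stats::rnorm, 12) - 0.05), 0.017)        # t branch
  expect_lt(abs(level(function(n) stats::rexp(n)^2, 25) - 0.05),
            0.017)                                             # rank branch
})

test_that("percent change handles reductions, identity and a zero baseline", {
  expect_equal(percent_change(rep(10, 5), rep(6, 5)), -40)
  expect_equal(percent_change(1:5, 1:5), 0)
  expect_warning(out <- percent_change(rep(0, 3), 1:3), "zero")
  expect_true(is.na(out))
  expect_true(attr(out, "flagged"))
})

test_that("the cohort ANOVA wrapper fits genotype-by-treatment designs", {
  df <- withr::with_seed(7, data.frame(
    atf = c(stats::rnorm(10, 0.12, 0.02), stats::rnorm(10, 0.29, 0.03),
            stats::rnorm(10, 0.12, 0.02), stats::rnorm(10, 0.15, 0.03)),
    genotype = rep(rep(c("control", "mutant"), each = 10), 2),
    treatment = rep(c("saline", "PTZ"), each = 20)))
  res <- cohort_anova(atf ~ genotype * treatment, df, pairwise = "genotype")
  tab <- res$anova[[1]]
  expect_identical(trimws(rownames(tab))[1:3],
                   c("genotype", "treatment", "genotype:treatment"))
  expect_lt(tab[["Pr(>F)"]][1], 0.001)
  expect_s3_class(res$pairwise, "pairwise.htest")
})
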