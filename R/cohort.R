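# Per-recording pipeline, cohort aggregation and the normality-gated group
# comparisons used for genotype and treatment contrasts.

#' Run the full apnea pipeline on one recording
#'
#' Chains [segment_breaths()], CORC estimation, [apnea_summary()] and
#' [classify_apneas()]; when an audio channel is present, clicks are detected,
#' the two-point clock map is fitted from the trigger and knock marks, and the
#' corrected click times assist apnea typing.  Without audio, typing falls
#' back to the plateau-only rule.
#'
#' @param rec a `sim_recording`, or any list with elements `pressure`
#'   (a [pressure_trace()]) and optionally `audio` (an [audio_trace()]).
#' @param corc_method `"poincare"` (default) or `"log_thd"`.
#' @param ... further arguments passed to [classify_apneas()].
#' @return list of class `apnea_analysis`: `series`, `corc`, `summary` (with
#'   `by_type`), `events`, `clicks` (corrected times or `NULL`), `sync`,
#'   `ventilation`.
#' @export
analyze_recording <- function(rec, corc_method = c("poincare", "log_thd"),
                              ...) {
  corc_method <- match.arg(corc_method)
  trace <- rec$pressure
  series <- segment_breaths(trace)
  corc <- if (corc_method == "poincare") corc_poincare(series)
          else corc_logthd(series)
  summ <- apnea_summary(series, corc)

  clicks_p <- NULL; sync <- NULL
  if (!is.null(rec$audio)) {
    cl <- detect_clicks(rec$audio)
    am <- detect_sync_marks(rec$audio$samples, rec$audio$sample_rate)
    pm <- c(trace$trigger_time %||% NA_real_, trace$knock_time %||% NA_real_)
    if (any(is.na(pm))) {
      pm <- detect_sync_marks(trace$samples, trace$sample_rate)
    }
    sync <- fit_sync(pm, am, pressure_rate = trace$sample_rate,
                     audio_rate = rec$audio$sample_rate)
    clicks_p <- apply_sync(sync, cl$time)
  }
  events <- classify_apneas(trace, series, corc, clicks = clicks_p, ...)
  summ <- atf_by_type(summ, events)
  vent <- ventilation_summary(series, trace$metadata$weight_g)
  structure(list(series = series, corc = corc, summary = summ,
                 events = events, clicks = clicks_p, sync = sync,
                 ventilation = vent),
            class = "apnea_analysis")
}

#' @export
print.apnea_analysis <- function(x, ...) {
  print(x$corc)
  print(x$summary)
  print(x$ventilation)
  invisible(x)
}

#' Per-pup cohort metrics table
#'
#' Runs [analyze_recording()] on every recording and assembles one row per
#' pup.  A recording that fails analysis is skipped with a warning and logged
#' in the `failures` attribute; the pipeline continues.
#'
#' @param recordings list of recordings (see [analyze_recording()]).
#' @param corc_method passed to [analyze_recording()].
#' @return data frame with columns `pup`, `atf`, `atf_bh`, `atf_cl`,
#'   `n_apneas`, `corc_s`, `f_r`, `v_t`, `v_e`; attribute `failures` is a
#'   character vector of error messages (named by pup index).
#' @export
per_pup_metrics <- function(recordings, corc_method = "poincare") {
  failures <- character(0)
  rows <- lapply(seq_along(recordings), function(i) {
    tryCatch({
      an <- analyze_recording(recordings[[i]], corc_method = corc_method)
      s <- an$summary
      data.frame(pup = i, atf = s$atf,
                 atf_bh = s$by_type[["breath_hold"]],
                 atf_cl = s$by_type[["central_like"]],
                 n_apneas = s$n_apneas, corc_s = s$corc_s,
                 f_r = an$ventilation$f_r, v_t = an$ventilation$v_t,
                 v_e = an$ventilation$v_e)
    }, error = function(e) {
      failures[[as.character(i)]] <<- conditionMessage(e)
      warning(sprintf("recording %d failed: %s", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pup = integer(0), atf = numeric(0), atf_bh = numeric(0),
                      atf_cl = numeric(0), n_apneas = integer(0),
                      corc_s = numeric(0), f_r = numeric(0), v_t = numeric(0),
                      v_e = numeric(0))
  }
  attr(out, "failures") <- failures
  out
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness and kurtosis statistics into
#' `K^2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2 df.
#' Requires n >= 20 for the kurtosis approximation to hold.
#'
#' @param x numeric sample.
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), Am Stat 44:316-321.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 20) stop("D'Agostino-Pearson test requires n >= 20", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Normality-gated two-group comparison
#'
#' Normality of each sample (of the paired differences for paired designs) is
#' tested with Shapiro-Wilk for n < 20 and the D'Agostino-Pearson omnibus
#' otherwise, at alpha = 0.05.  When normality holds, a Student's t test
#' (paired or unpaired) is used; otherwise Mann-Whitney (unpaired) or Wilcoxon
#' signed-rank (paired).
#'
#' @param x,y numeric samples, each with n >= 3.
#' @param paired paired design?
#' @param alpha normality-gate level.
#' @return list of class `group_comparison`: `test`, `statistic`, `p_value`,
#'   `df` (NA for rank tests), `n`, `paired`, `normal` (gate outcome).
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  norm_p <- function(v) {
    if (stats::sd(v) == 0) return(0)
    if (length(v) < 20) stats::shapiro.test(v)$p.value
    else dagostino_pearson(v)$p.value
  }
  if (paired) {
    stopifnot(length(x) == length(y))
    if (stats::sd(x - y) == 0) {
      # degenerate paired design: no within-pair variation, no evidence of a
      # difference
      return(structure(list(test = "paired t", statistic = 0, p_value = 1,
                            df = length(x) - 1, n = c(length(x), length(y)),
                            paired = TRUE, normal = TRUE),
                       class = "group_comparison"))
    }
  }
  normal <- if (paired) {
    norm_p(x - y) >= alpha
  } else {
    norm_p(x) >= alpha && norm_p(y) >= alpha
  }
  if (normal) {
    ht <- stats::t.test(x, y, paired = paired)
    test <- if (paired) "paired t" else "unpaired t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter %||% NA_real_),
                 n = c(length(x), length(y)), paired = paired,
                 normal = normal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, p = %.4g (n = %s)\n", x$test,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Percent change of the group mean
#'
#' `100 * (mean(post) - mean(pre)) / mean(pre)`, the relative-change statistic
#' used for treatment effects (negative values are reductions).
#'
#' @param pre,post numeric samples (matched lengths for paired designs).
#' @return percent change; `NA` with attribute `flagged = TRUE` when
#'   `mean(pre)` is zero.
#' @export
percent_change <- function(pre, post) {
  mp <- mean(pre)
  if (mp == 0) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    warning("mean of the pre sample is zero; percent change undefined")
    return(out)
  }
  100 * (mean(post) - mp) / mp
}

#' Two-way cohort ANOVA with Bonferroni pairwise follow-up
#'
#' Thin wrapper over [stats::aov()] for cohort-by-treatment designs, with
#' optional Bonferroni-corrected pairwise t tests on one factor.  Supporting
#' plumbing around the apnea statistics, delegating entirely to the standard
#' formulations.
#'
#' @param formula model formula, e.g. `atf ~ genotype * treatment`.
#' @param data cohort table.
#' @param pairwise optional name of a factor for Bonferroni pairwise t tests.
#' @return list with `anova` (the aov fit summary) and `pairwise`.
#' @export
cohort_anova <- function(formula, data, pairwise = NULL) {
  fit <- stats::aov(formula, data = data)
  pw <- NULL
  if (!is.null(pairwise)) {
    resp <- stats::model.frame(formula, data)[[1]]
    pw <- stats::pairwise.t.test(resp, data[[pairwise]],
                                 p.adjust.method = "bonferroni")
  }
  list(anova = summary(fit), pairwise = pw)
}
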