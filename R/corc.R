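# Cut-off respiratory cycle (CORC) estimation and apnea quantification.
#
# An apneic cycle is an isolated respiratory cycle longer than the CORC, the
# duration threshold that separates the repetitive-breathing population
# (clustered on the Poincaré-plot diagonal) from isolated long cycles.

#' Consecutive cycle-duration pairs for a Poincaré plot
#'
#' @param series a `cycle_series` with at least two cycles.
#' @return data frame with columns `t_n`, `t_n1`: duration of cycle n against
#'   cycle n + 1.  Regular breathing clusters on the diagonal near the origin;
#'   each isolated apneic cycle contributes two off-diagonal points.
#' @export
poincare_points <- function(series) {
  d <- series$duration
  if (length(d) < 2) stop("need at least 2 cycles", call. = FALSE)
  data.frame(t_n = d[-length(d)], t_n1 = d[-1])
}

corc_estimate <- function(corc, method, diagnostics, flagged = FALSE) {
  structure(list(corc = corc, method = method, diagnostics = diagnostics,
                 flagged = flagged),
            class = "corc_estimate")
}

#' @export
print.corc_estimate <- function(x, ...) {
  cat(sprintf("CORC estimate: %.3f s (method: %s%s)\n", x$corc, x$method,
              if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' CORC from the Poincaré-plot repetitive cluster
#'
#' Cycles whose duration is within tolerance of both neighbours form the
#' repetitive set (regular breathing cycles followed and preceded by cycles of
#' about the same duration); its duration distribution is summarised by a
#' single Gaussian and the CORC is placed at `mean + k * SD`, the boundary
#' beyond which isolated cycles are counted apneic.  The neighbour tolerance
#' is `neighbour_mult` robust SDs of the first differences of cycle duration,
#' so it adapts to each record's own variability.
#'
#' @param series a `cycle_series` with at least 30 cycles.
#' @param k number of SDs above the repetitive-cluster mean (default 4).
#' @param neighbour_mult neighbour tolerance in robust SDs of first
#'   differences.
#' @return a `corc_estimate` with diagnostics (cluster mean, SD, size,
#'   tolerance).
#' @export
corc_poincare <- function(series, k = 4, neighbour_mult = 3) {
  d <- series$duration
  n <- length(d)
  if (n < 30) stop("need at least 30 cycles for CORC estimation", call. = FALSE)
  s <- stats::mad(diff(d))
  tol <- max(neighbour_mult * s, 1e-6)
  near <- abs(diff(d)) < tol      # near[i]: cycles i and i+1 similar
  rep_set <- c(near[1], near[-1] & near[-(n - 1)], near[n - 1])
  if (sum(rep_set) < 10) {
    stop(sprintf(paste0("no repetitive cluster identifiable ",
                        "(%d of %d cycles within tolerance %.3g s)"),
                 sum(rep_set), n, tol), call. = FALSE)
  }
  mu <- mean(d[rep_set])
  sdv <- stats::sd(d[rep_set])
  corc_estimate(mu + k * sdv, "poincare",
                list(rep_mean = mu, rep_sd = sdv, n_repetitive = sum(rep_set),
                     tolerance = tol, k = k))
}

atf_at <- function(durations, total, thd) {
  vapply(thd, function(th) sum(durations[durations > th]) / total, numeric(1))
}

#' CORC from the ATF versus log-threshold relation
#'
#' For thresholds `ThD` inside the apneic duration range the apneic time
#' fraction `ATF(ThD)` falls linearly with `log(ThD)`.  The line is fitted on
#' the clearly apneic range (`ThD >= fit_mult * median duration`) and the
#' threshold is extrapolated downward along a descending logarithmic grid; the
#' CORC is the largest `ThD` at which the observed ATF departs from the fit by
#' more than `depart_sd` residual SDs.  When the series has no long cycles
#' (none beyond `fit_mult` times the median) the grid floor is returned with
#' `flagged = TRUE`.
#'
#' @param series a `cycle_series` with at least 30 cycles.
#' @param n_grid number of grid points (log-spaced from `grid_top` down to
#'   just above the repetitive-cluster mean).
#' @param grid_top top of the ThD grid (s).
#' @param fit_mult multiple of the median duration above which cycles are
#'   treated as clearly apneic for the fit.
#' @param depart_sd departure criterion in residual SDs.
#' @return a `corc_estimate`; diagnostics retain the grid, the ATF values and
#'   the fit.
#' @export
corc_logthd <- function(series, n_grid = 40, grid_top = 8, fit_mult = 3,
                        depart_sd = 3) {
  d <- series$duration
  n <- length(d)
  if (n < 30) stop("need at least 30 cycles for CORC estimation", call. = FALSE)
  total <- attr(series, "total_duration")
  med <- stats::median(d)
  rep_mean <- mean(d[d < fit_mult * med])
  floor_th <- 1.02 * rep_mean
  grid <- exp(seq(log(grid_top), log(floor_th), length.out = n_grid))
  atf <- atf_at(d, total, grid)

  if (!any(d > fit_mult * med)) {
    return(corc_estimate(floor_th, "log_thd",
                         list(grid = grid, atf = atf, fit = NULL,
                              note = "no cycles beyond fit range"),
                         flagged = TRUE))
  }
  in_fit <- grid >= fit_mult * med
  if (sum(in_fit) < 5) in_fit <- seq_along(grid) <= 5
  fit <- stats::lm(atf[in_fit] ~ log(grid[in_fit]))
  resid_sd <- max(stats::sd(stats::residuals(fit)), 1e-6)
  pred <- fit$coefficients[1] + fit$coefficients[2] * log(grid)
  lower <- which(!in_fit)
  depart <- lower[abs(atf[lower] - pred[lower]) > depart_sd * resid_sd]
  if (!length(depart)) {
    return(corc_estimate(floor_th, "log_thd",
                         list(grid = grid, atf = atf,
                              slope = unname(fit$coefficients[2]),
                              resid_sd = resid_sd,
                              note = "no departure down to the grid floor"),
                         flagged = TRUE))
  }
  corc <- grid[min(depart)]   # grid is descending: first departure = largest ThD
  corc_estimate(corc, "log_thd",
                list(grid = grid, atf = atf,
                     slope = unname(fit$coefficients[2]),
                     resid_sd = resid_sd, fit_range = range(grid[in_fit])))
}

#' Label cycles as repetitive or apneic
#'
#' @param series a `cycle_series`.
#' @param corc a `corc_estimate` (or a plain duration threshold in seconds).
#' @return factor of length `nrow(series)` with levels
#'   `c("repetitive", "apneic")`; apneic means duration strictly greater than
#'   the CORC.
#' @export
label_cycles <- function(series, corc) {
  th <- if (inherits(corc, "corc_estimate")) corc$corc else corc
  factor(ifelse(series$duration > th, "apneic", "repetitive"),
         levels = c("repetitive", "apneic"))
}

#' Apnea counts and apneic time fraction
#'
#' The ATF is the summed duration of apneic cycles divided by the total
#' recorded duration; the apnea count is the number of cycles longer than the
#' CORC.  Runs of consecutive apneic cycles (which violate the isolation
#' assumption behind the CORC definition) are counted individually but
#' flagged.
#'
#' @inheritParams label_cycles
#' @return an `apnea_summary`: `atf`, `n_apneas`, `durations`, `indices`,
#'   `consecutive` flag, `corc_s`, `total_duration`.
#' @export
apnea_summary <- function(series, corc) {
  labels <- label_cycles(series, corc)
  idx <- which(labels == "apneic")
  total <- attr(series, "total_duration")
  durs <- series$duration[idx]
  structure(list(atf = sum(durs) / total, n_apneas = length(idx),
                 durations = durs, indices = idx,
                 consecutive = any(diff(idx) == 1L),
                 corc_s = if (inherits(corc, "corc_estimate")) corc$corc
                          else corc,
                 total_duration = total),
            class = "apnea_summary")
}

#' @export
print.apnea_summary <- function(x, ...) {
  cat(sprintf("Apnea summary: ATF %.1f%%, %d apneas (CORC %.3f s)%s\n",
              100 * x$atf, x$n_apneas, x$corc_s,
              if (isTRUE(x$consecutive)) " [consecutive apneic cycles]" else ""))
  if (!is.null(x$by_type)) {
    cat(sprintf("  breath-hold %.1f%%, central-like %.1f%%\n",
                100 * x$by_type[["breath_hold"]],
                100 * x$by_type[["central_like"]]))
  }
  invisible(x)
}
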