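#' Construct a simulation profile for a genotype/treatment cohort
#'
#' A `sim_profile` bundles the generative parameters of one cohort of neonatal
#' mouse pups: the regular-breathing cycle distribution, the per-cycle apnea
#' probabilities and duration ranges for the two apnea types, the waveform
#' parameters of breath holds (retained-volume plateau, terminal click), vocal
#' bout and click-emission rates for joint audio recordings, sensor noise, and
#' the audio-vs-pressure clock drift.
#'
#' @param name profile label.
#' @param mu_reg mean regular cycle duration (s).
#' @param sigma_reg SD of regular cycle duration (s).
#' @param ti_fraction inspiratory fraction Ti/(Ti+Te) of a regular cycle.
#' @param vt_mean tidal amplitude (µL).
#' @param p_bh per-cycle probability that a cycle is a breath-holding apnea.
#' @param p_cl per-cycle probability that a cycle is a central-like apnea.
#' @param dur_bh length-2 range (s) of breath-hold cycle durations.
#' @param dur_cl length-2 range (s) of central-like cycle durations.
#' @param plateau_frac retained volume during a breath hold, as a fraction of
#'   the inspiratory amplitude.
#' @param p_click_bh probability that a breath hold ends with a click.
#' @param vocal_rate vocal bouts per minute (0 disables vocal breathing).
#' @param p_click_vocal click probability per vocal lung-compression event.
#' @param p_click_eupnea stray click probability per eupneic cycle.
#' @param p_click_central stray click probability per central-like apnea.
#' @param noise_sd additive pressure noise SD, as a fraction of `vt_mean`.
#' @param drift_ppm audio-vs-pressure clock drift (parts per million).
#' @param weight_g pup mass (g).
#' @param resume_prob probability that a breath hold carries resuming
#'   inspiratory efforts of growing amplitude on its plateau.
#' @return an object of class `sim_profile`.
#' @seealso [build_profile()] for the calibrated registry,
#'   [expected_summary()] for the closed-form apneic time fraction.
#' @export
sim_profile <- function(name = "custom",
                        mu_reg = 0.4, sigma_reg = 0.03, ti_fraction = 0.35,
                        vt_mean = 8, p_bh = 0, p_cl = 0,
                        dur_bh = c(1.5, 3.5), dur_cl = c(1.2, 2.8),
                        plateau_frac = 0.8, p_click_bh = 0.695,
                        vocal_rate = 0, p_click_vocal = 0.85,
                        p_click_eupnea = 0, p_click_central = 0,
                        noise_sd = 0.03, drift_ppm = 50, weight_g = 1.4,
                        resume_prob = 0.5) {
  p <- list(name = name, mu_reg = mu_reg, sigma_reg = sigma_reg,
            ti_fraction = ti_fraction, vt_mean = vt_mean,
            p_bh = p_bh, p_cl = p_cl, dur_bh = dur_bh, dur_cl = dur_cl,
            plateau_frac = plateau_frac, p_click_bh = p_click_bh,
            vocal_rate = vocal_rate, p_click_vocal = p_click_vocal,
            p_click_eupnea = p_click_eupnea, p_click_central = p_click_central,
            noise_sd = noise_sd, drift_ppm = drift_ppm, weight_g = weight_g,
            resume_prob = resume_prob)
  class(p) <- "sim_profile"
  validate_sim_profile(p)
  p
}

validate_sim_profile <- function(p) {
  probs <- c(p$p_bh, p$p_cl, p$p_click_bh, p$p_click_vocal,
             p$p_click_eupnea, p$p_click_central, p$resume_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$p_bh + p$p_cl >= 1) stop("p_bh + p_cl must be < 1", call. = FALSE)
  if (p$mu_reg <= 0 || p$sigma_reg < 0) stop("invalid regular-cycle parameters",
                                             call. = FALSE)
  if (p$ti_fraction <= 0 || p$ti_fraction >= 1) {
    stop("ti_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (p$plateau_frac < 0 || p$plateau_frac > 1) {
    stop("plateau_frac must lie in [0, 1]", call. = FALSE)
  }
  floor_apnea <- p$mu_reg + 3 * p$sigma_reg
  for (rng in list(p$dur_bh, p$dur_cl)) {
    if (length(rng) != 2 || rng[1] >= rng[2]) {
      stop("apneic duration ranges must be increasing length-2 vectors",
           call. = FALSE)
    }
    if (rng[1] <= floor_apnea) {
      stop("apneic durations must lie strictly above mu_reg + 3*sigma_reg",
           call. = FALSE)
    }
  }
  if (abs(p$drift_ppm) > 200) stop("|drift_ppm| must be <= 200", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_profile <- function(x, ...) {
  es <- expected_summary(x)
  cat("Simulation profile:", x$name, "\n")
  cat(sprintf("  regular cycles: %.3f +/- %.3f s, V_T %.1f uL\n",
              x$mu_reg, x$sigma_reg, x$vt_mean))
  cat(sprintf("  apnea probabilities: breath-hold %.4f, central-like %.4f\n",
              x$p_bh, x$p_cl))
  cat(sprintf("  expected ATF: total %.1f%% (bh %.1f%%, cl %.1f%%)\n",
              100 * es$total, 100 * es$breath_hold, 100 * es$central_like))
  if (x$vocal_rate > 0) {
    cat(sprintf("  vocal bouts: %.2f / min, click p(vocal) %.2f\n",
                x$vocal_rate, x$p_click_vocal))
  }
  invisible(x)
}

#' Closed-form expected apneic time fraction of a profile
#'
#' For the stationary cycle mixture with per-cycle type probabilities
#' \eqn{p_t} and mean durations \eqn{E[D_t]}, the expected fraction of
#' recording time spent in apneas of type \eqn{t} is
#' \deqn{ATF_t = p_t E[D_t] / ((1 - p_{bh} - p_{cl}) \mu_{reg}
#'        + p_{bh} E[D_{bh}] + p_{cl} E[D_{cl}]).}
#' This is the analytic twin of the simulator and the quantity the detection
#' pipeline estimates.
#'
#' @param profile a [sim_profile()].
#' @return list with `total`, `breath_hold`, `central_like` (fractions) and
#'   `mean_cycle_s`, the stationary mean cycle duration (the denominator).
#' @export
expected_summary <- function(profile) {
  validate_sim_profile(profile)
  e_bh <- mean(profile$dur_bh)
  e_cl <- mean(profile$dur_cl)
  denom <- (1 - profile$p_bh - profile$p_cl) * profile$mu_reg +
    profile$p_bh * e_bh + profile$p_cl * e_cl
  atf_bh <- profile$p_bh * e_bh / denom
  atf_cl <- profile$p_cl * e_cl / denom
  list(total = atf_bh + atf_cl, breath_hold = atf_bh, central_like = atf_cl,
       mean_cycle_s = denom)
}

# Invert the closed form: per-cycle probabilities that realise target per-type
# apneic time fractions.  Derivation: with a = a_bh + a_cl,
#   T = mu / ((1 - a) + mu * (a_bh/E_bh + a_cl/E_cl)),  p_t = a_t * T / E_t.
atf_to_probs <- function(a_bh, a_cl, mu_reg, e_bh, e_cl) {
  a <- a_bh + a_cl
  stopifnot(a_bh >= 0, a_cl >= 0, a < 1)
  tbar <- mu_reg / ((1 - a) + mu_reg * (a_bh / e_bh + a_cl / e_cl))
  c(p_bh = a_bh * tbar / e_bh, p_cl = a_cl * tbar / e_cl)
}

# Calibrate vocal bout rate and stray click probabilities so the expected
# click-context proportions match `targets` (%, order vocal/bh/eupnea/central),
# taking the breath-hold click channel (rate * p_click_bh) as the anchor.
calibrate_clicks <- function(p, targets = c(vocal = 81.5, breath_hold = 15.0,
                                            eupnea = 2.2, central = 1.1),
                             cycles_per_bout = 5) {
  es <- expected_summary(p)
  d <- es$mean_cycle_s
  n_bh <- 60 * p$p_bh / d * p$p_click_bh           # bh clicks / min
  w <- targets / targets[["breath_hold"]]
  n_voc <- n_bh * w[["vocal"]]
  n_eup <- n_bh * w[["eupnea"]]
  n_cen <- n_bh * w[["central"]]
  p$vocal_rate <- n_voc / (p$p_click_vocal * cycles_per_bout)
  c_reg <- 60 * (1 - p$p_bh - p$p_cl) / d           # regular cycles / min
  eup_cycles <- c_reg - cycles_per_bout * p$vocal_rate
  stopifnot(eup_cycles > 0)
  p$p_click_eupnea <- n_eup / eup_cycles
  cen_events <- 60 * p$p_cl / d
  p$p_click_central <- if (cen_events > 0) n_cen / cen_events else 0
  validate_sim_profile(p)
  p
}

profile_registry <- function() {
  base <- function(name, a_bh, a_cl, ...) {
    pr <- sim_profile(name = name, ...)
    pp <- atf_to_probs(a_bh, a_cl, pr$mu_reg, mean(pr$dur_bh), mean(pr$dur_cl))
    pr$p_bh <- unname(pp["p_bh"])
    pr$p_cl <- unname(pp["p_cl"])
    validate_sim_profile(pr)
    pr
  }
  wt <- base("wt_joint_audio", a_bh = 0.097, a_cl = 0.040)
  wt <- calibrate_clicks(wt)
  list(
    control_P0_12h    = base("control_P0_12h",    a_bh = 0.083, a_cl = 0.040),
    mutant_n4A_P0_12h = base("mutant_n4A_P0_12h", a_bh = 0.226, a_cl = 0.067),
    null_LacZ         = base("null_LacZ",         a_bh = 0.017, a_cl = 0.040),
    wt_joint_audio    = wt,
    dreadd_baseline   = base("dreadd_baseline",   a_bh = 0.035, a_cl = 0.015)
  )
}

#' Retrieve a registered cohort profile
#'
#' The registry holds generative profiles calibrated so that the closed-form
#' [expected_summary()] reproduces the published cohort means: mutant pups
#' (total ATF 29.3%, breath-hold component 22.6%), their controls (12.3% /
#' 8.3%), null mutants (breath-hold 1.7%, central-like set to the control
#' value), a wild-type joint audio-plethysmography profile (breath-hold ATF
#' 9.7%, 69.5% of breath holds clicking, click contexts 81.5/15.0/2.2/1.1%),
#' and a chemogenetic pre-injection baseline (total ATF 5%).
#'
#' @param name one of `names(profile_registry())`:
#'   `"control_P0_12h"`, `"mutant_n4A_P0_12h"`, `"null_LacZ"`,
#'   `"wt_joint_audio"`, `"dreadd_baseline"`.
#' @return a [sim_profile()].
#' @examples
#' pr <- build_profile("mutant_n4A_P0_12h")
#' expected_summary(pr)$breath_hold  # 0.226
#' @export
build_profile <- function(name) {
  reg <- profile_registry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown profile '%s'; registered profiles: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  reg[[name]]
}

#' Apply a pharmacological treatment transform to a profile
#'
#' `"PTZ"` (GABA-A antagonist at a sub-convulsive dose) shortens the regular
#' cycle (breathing-rate increase) and scales the breath-hold probability down
#' so that the expected total apneic time fraction is halved — a reduction
#' exceeding the reported 40%.  `"CNO"` (chemogenetic activation of inhibitory
#' neurons) scales both apnea channels up to a five-fold expected total ATF.
#' `"saline"` is the identity.  Scale factors are obtained by inverting the
#' closed form of [expected_summary()].
#'
#' @param profile a [sim_profile()].
#' @param treatment `"PTZ"`, `"CNO"` or `"saline"`.
#' @return the transformed profile.
#' @export
apply_treatment <- function(profile, treatment = c("PTZ", "CNO", "saline")) {
  treatment <- match.arg(treatment)
  pre <- expected_summary(profile)
  out <- profile
  if (treatment == "saline") return(out)
  if (treatment == "PTZ") {
    out$mu_reg <- 0.85 * profile$mu_reg
    target_total <- 0.5 * pre$total
    f <- function(p_bh) {
      q <- out; q$p_bh <- p_bh
      expected_summary(q)$total - target_total
    }
    upper <- min(profile$p_bh, 1 - out$p_cl - 1e-6)
    if (f(0) >= 0) {
      out$p_bh <- 0   # central channel alone already exceeds the target
    } else {
      out$p_bh <- stats::uniroot(f, c(0, upper), tol = 1e-12)$root
    }
    out$name <- paste0(profile$name, "+PTZ")
  } else {  # CNO
    pp <- atf_to_probs(5 * pre$breath_hold, 5 * pre$central_like,
                       out$mu_reg, mean(out$dur_bh), mean(out$dur_cl))
    out$p_bh <- unname(pp["p_bh"])
    out$p_cl <- unname(pp["p_cl"])
    out$name <- paste0(profile$name, "+CNO")
  }
  validate_sim_profile(out)
  out
}

#' Write / read a profile as JSON or YAML
#'
#' @param profile a [sim_profile()].
#' @param path output file; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `write_profile` returns `path` invisibly; `read_profile` returns the
#'   profile.
#' @export
write_profile <- function(profile, path) {
  obj <- unclass(profile)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 15)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(sim_profile, obj)
}
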