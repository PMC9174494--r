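# Plain-text readers/writers for the pipeline's tabular interfaces.

#' Read / write a pressure trace as CSV or WAV
#'
#' CSV traces carry a `time,pressure` header; WAV traces use
#' [read_wav()]/[write_wav()] (float32) with the sample rate from the header.
#'
#' @param trace a [pressure_trace()].
#' @param path file path (`.csv` or `.wav`).
#' @return `read_pressure` returns a [pressure_trace()]; writers return `path`
#'   invisibly.
#' @export
write_pressure <- function(trace, path) {
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    write_wav(trace$samples, trace$sample_rate, path, bits = 32)
  } else {
    tt <- (seq_along(trace$samples) - 1) / trace$sample_rate
    utils::write.csv(data.frame(time = tt, pressure = trace$samples), path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_pressure
#' @param sample_rate required for CSV input only when the time column is
#'   absent.
#' @param ... passed to [pressure_trace()] (sync marks, metadata).
#' @export
read_pressure <- function(path, sample_rate = NULL, ...) {
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    w <- read_wav(path)
    return(pressure_trace(w$samples, w$sample_rate, ...))
  }
  df <- utils::read.csv(path)
  if ("time" %in% names(df) && nrow(df) > 1) {
    sample_rate <- 1 / stats::median(diff(df$time))
  }
  if (is.null(sample_rate)) stop("sample_rate required for this CSV",
                                 call. = FALSE)
  pressure_trace(df$pressure, sample_rate, ...)
}

#' Write a cycle table, click table or apnea summary
#'
#' Cycle tables are CSV with columns
#' `onset_s,Ti_s,Te_s,duration_s,amplitude_uL,end_exp_uL`; click tables are
#' `time_s,duration_ms,energy_db`; apnea summaries are JSON
#' (`corc_s, method, atf, n_apneas, durations`).
#'
#' @param series,clicks,summary objects from [segment_breaths()],
#'   [detect_clicks()], [apnea_summary()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(series, path) {
  utils::write.csv(data.frame(onset_s = series$onset, Ti_s = series$ti,
                              Te_s = series$te, duration_s = series$duration,
                              amplitude_uL = series$amplitude,
                              end_exp_uL = series$end_exp),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cycles_csv
#' @export
write_clicks_csv <- function(clicks, path) {
  utils::write.csv(data.frame(time_s = clicks$time,
                              duration_ms = 1000 * clicks$duration,
                              energy_db = clicks$energy_db),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cycles_csv
#' @export
write_apnea_json <- function(summary, path) {
  jsonlite::write_json(list(corc_s = summary$corc_s, atf = summary$atf,
                            n_apneas = summary$n_apneas,
                            durations = summary$durations,
                            by_type = as.list(summary$by_type %||% NULL)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write simulation ground truth as CSV
#'
#' One row per cycle (`onset_s,duration_s,kind`) plus, for clicking cycles,
#' the click time (`click_s`, NA otherwise).
#'
#' @param truth a `ground_truth`.
#' @param path output file.
#' @export
write_truth_csv <- function(truth, path) {
  cyc <- truth$cycles
  click_s <- rep(NA_real_, nrow(cyc))
  if (length(truth$clicks)) {
    ix <- findInterval(truth$clicks, cyc$onset)
    click_s[ix] <- truth$clicks
  }
  utils::write.csv(data.frame(onset_s = cyc$onset, duration_s = cyc$duration,
                              kind = cyc$kind, click_s = click_s),
                   path, row.names = FALSE)
  invisible(path)
}
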