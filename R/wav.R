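# Minimal mono RIFF/WAVE reader and writer (16-bit PCM and 32-bit IEEE
# float), sufficient for pressure and ultrasound-audio traces.

#' Read / write mono WAV files
#'
#' `read_wav` parses a mono RIFF/WAVE file (16-bit PCM or 32-bit float) and
#' returns the samples with their rate; `write_wav` writes one.  16-bit data
#' are mapped to/from [-1, 1].
#'
#' @param path file path.
#' @return `read_wav`: list with `samples` (numeric, [-1, 1] for PCM) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  if (riff != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- rawToChar(readBin(con, "raw", 4))
  if (wave != "WAVE") stop("not a WAVE file", call. = FALSE)

  fmt <- NULL; samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little"),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (tag == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk", call. = FALSE)
      if (fmt$channels != 1) stop("only mono WAV supported", call. = FALSE)
      if (fmt$format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                           endian = "little") / 32767
      } else if (fmt$format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "numeric", size / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)", call. = FALSE)
      }
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  list(samples = samples, sample_rate = fmt$rate)
}

#' @rdname read_wav
#' @param samples numeric samples (clipped to [-1, 1] for 16-bit output).
#' @param sample_rate sampling rate (Hz).
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  n <- length(samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmax(-1, pmin(1, samples)) * 32767)), con, 2,
             endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}
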