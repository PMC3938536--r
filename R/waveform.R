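#' Construct a waveform
#'
#' A `waveform` is the package's audio container: a numeric vector of
#' dimensionless sample amplitudes in `[-1, 1]` plus a sampling rate in Hz.
#' Duration is derived as `length(samples) / rate`.
#'
#' @param samples Numeric vector of finite sample amplitudes, nominally in
#'   `[-1, 1]`.
#' @param rate Sampling frequency in Hz (a single positive number).
#' @return An object of class `waveform` with elements `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 220 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' wave_duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop_validation("'rate' must be a single positive number, got: ",
                    deparse(substitute(rate)))
  if (length(samples) == 0L)
    stop_validation("'samples' is empty")
  if (!all(is.finite(samples)))
    stop_validation("'samples' contains non-finite values")
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz = %.3f s, peak %.3f>\n",
              length(x$samples), x$rate, wave_duration(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

#' Time intervals
#'
#' Intervals are half-open `[start, end)` spans in seconds, stored as a
#' data frame with columns `start` and `end`. All silence, vowel and
#' exclusion boundaries in the package use this representation.
#'
#' @param start,end Numeric vectors of equal length; `0 <= start < end`.
#' @return A data frame with columns `start`, `end` (seconds).
#' @export
intervals <- function(start = numeric(), end = numeric()) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end))
    stop_validation("'start' and 'end' differ in length")
  if (length(start) && (any(!is.finite(start)) || any(!is.finite(end))))
    stop_validation("interval boundaries must be finite")
  if (length(start) && any(start < 0))
    stop_validation("interval start times must be >= 0")
  bad <- which(end <= start)
  if (length(bad))
    stop_validation("reversed or zero-length interval at row ",
                    paste(bad, collapse = ", "),
                    " (end must exceed start)")
  data.frame(start = start, end = end)
}

# internal: quick structural check for an intervals-shaped data frame
as_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L))
    return(intervals())
  if (!is.data.frame(x) || !all(c("start", "end") %in% names(x)))
    stop_validation("expected a data frame with columns 'start' and 'end'")
  intervals(x$start, x$end)
}

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file containing 16-bit integer PCM or 32-bit IEEE
#' float samples at any rate. Multi-channel files are averaged to mono;
#' integer samples are rescaled to `[-1, 1]` by 1/32768.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    stop_validation("WAV file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_validation("not a RIFF file (bad magic '", riff, "'): ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_validation("RIFF file is not WAVE (form type '", wave, "'): ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        rate     = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                           endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt))
    stop_validation("missing 'fmt ' chunk: ", path)
  if (is.null(data_raw))
    stop_validation("missing 'data' chunk: ", path)

  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4,
                 endian = "little")
  } else {
    stop_validation("unsupported WAV encoding: format tag ", fmt$format,
                    ", ", fmt$bits, " bits (need PCM16 or float32)")
  }
  nch <- max(1L, fmt$channels)
  if (nch > 1L) {
    n <- (length(x) %/% nch) * nch
    x <- colMeans(matrix(x[seq_len(n)], nrow = nch))
  }
  waveform(x, fmt$rate)
}

#' Write a waveform to a WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param bits Either 16 (integer PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16L) {
  stopifnot(inherits(w, "waveform"))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 32L))
    stop_validation("'bits' must be 16 or 32")
  n <- length(w$samples)
  bytes_per <- bits %/% 8L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(round(w$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(w$rate) * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(w$samples * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

# error helpers: validation errors carry their own class so the CLI can map
# them to exit code 2 (vs 3 for computation errors)
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("ppa_validation_error",
                                             "error", "condition")))
}
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("ppa_degenerate_error",
                                             "ppa_validation_error",
                                             "error", "condition")))
}
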