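#' Intensity contour of a waveform
#'
#' Computes a short-time intensity contour: the waveform is cut into
#' Hann-tapered frames of length `window_s` stepped by `hop_s`, and each
#' frame's intensity is `10 * log10` of its taper-weighted mean squared
#' amplitude, floored at `floor_db`. Intensity is therefore in dB relative
#' to full scale (a constant full-scale signal sits at 0 dB); recordings
#' are uncalibrated so only relative levels are meaningful, and all
#' downstream silence thresholds are range-relative.
#'
#' Frame centres run from `window_s / 2` to `duration - window_s / 2`, so
#' the contour covers the span where a full analysis window fits.
#'
#' @param w A [waveform()].
#' @param window_s Analysis window length in seconds (default 0.032).
#' @param hop_s Frame step in seconds (default 0.008).
#' @param floor_db Lower bound applied to frame values in dB (default -96,
#'   the 16-bit noise floor).
#' @return An object of class `intensity_contour`: a list with `times`
#'   (frame centres, seconds), `values` (dB), `window_s`, `hop_s`,
#'   `floor_db`.
#' @examples
#' w <- waveform(rep(c(1, -1), 4000), 8000)
#' ic <- intensity_contour(w)
#' range(ic$values)  # constant |x| = 1 signal: ~0 dB everywhere
#' @export
intensity_contour <- function(w, window_s = 0.032, hop_s = 0.008,
                              floor_db = -96) {
  stopifnot(inherits(w, "waveform"))
  if (window_s <= 0 || hop_s <= 0)
    stop_validation("'window_s' and 'hop_s' must be positive")
  dur <- wave_duration(w)
  if (dur < window_s)
    stop_validation("waveform (", signif(dur, 4), " s) is shorter than one ",
                    "analysis window (", window_s, " s)")
  win_n <- max(2L, round(window_s * w$rate))
  hop_n <- max(1L, round(hop_s * w$rate))
  n <- length(w$samples)
  n_frames <- (n - win_n) %/% hop_n + 1L
  taper <- hann_window(win_n)
  taper <- taper / sum(taper)
  x2 <- w$samples^2
  starts <- (seq_len(n_frames) - 1L) * hop_n
  ms <- vapply(starts, function(s0) sum(taper * x2[(s0 + 1L):(s0 + win_n)]),
               numeric(1))
  vals <- 10 * log10(pmax(ms, 10^(floor_db / 10)))
  centres <- (starts + (win_n - 1) / 2) / w$rate + 0.5 / w$rate
  structure(list(times = centres, values = vals,
                 window_s = win_n / w$rate, hop_s = hop_n / w$rate,
                 floor_db = floor_db),
            class = "intensity_contour")
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' @export
print.intensity_contour <- function(x, ...) {
  cat(sprintf(
    "<intensity_contour: %d frames, %.0f ms window / %.0f ms hop, %.1f..%.1f dB>\n",
    length(x$times), x$window_s * 1000, x$hop_s * 1000,
    min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.intensity_contour <- function(x, ...) {
  data.frame(time_s = x$times, db = x$values)
}

#' Peak intensity within an interval
#'
#' Maximum contour value among frames whose centre falls in the half-open
#' interval `[start, end)`.
#'
#' @param contour An [intensity_contour()].
#' @param start,end Interval boundaries in seconds, `start < end`.
#' @return Peak intensity in dB.
#' @export
peak_db <- function(contour, start, end) {
  stopifnot(inherits(contour, "intensity_contour"))
  if (!is.finite(start) || !is.finite(end) || end <= start)
    stop_validation("invalid query interval [", start, ", ", end,
                    "): end must exceed start")
  sel <- contour$times >= start & contour$times < end
  if (!any(sel))
    stop_validation("no frame centre falls in [", start, ", ", end, ")")
  max(contour$values[sel])
}
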