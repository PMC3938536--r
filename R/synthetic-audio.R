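# run expr under set.seed(seed) without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# band-limited noise at a target RMS level (dB full scale): white noise
# through a short moving average, renormalized
noise_at_db <- function(n, level_db, smooth = 5L) {
  x <- stats::rnorm(n)
  if (smooth > 1L) {
    x <- stats::filter(x, rep(1 / smooth, smooth), sides = 2)
    x[is.na(x)] <- 0
  }
  x <- as.numeric(x)
  rms <- sqrt(mean(x^2))
  x / rms * 10^(level_db / 20)
}

#' Synthesize pseudo-speech with planted silences
#'
#' Builds a waveform from an alternating segment specification: `speech`
#' segments are band-limited noise set to the requested RMS level (dB
#' full scale); `silence` segments are floor-level noise `floor_offset_db`
#' below the quietest speech segment (40 dB by default, so thresholding
#' is unambiguous). The true silence intervals are returned alongside the
#' audio; identical seeds give bit-identical output.
#'
#' @param segments Data frame with columns `kind` (`"speech"` /
#'   `"silence"`), `duration_s` (> 0) and `level_db` (speech RMS level,
#'   dB full scale; ignored for silences). Must start and end with
#'   speech.
#' @param rate Sampling rate in Hz (default 48000).
#' @param seed Optional integer seed.
#' @param floor_offset_db Offset of the silence floor below the quietest
#'   speech level (default 40).
#' @return List with `waveform` ([waveform()]) and `truth` (data frame of
#'   planted silence intervals).
#' @export
synth_audio <- function(segments, rate = 48000, seed = NULL,
                        floor_offset_db = 40) {
  segments <- as.data.frame(segments)
  if (!all(c("kind", "duration_s") %in% names(segments)) ||
      !nrow(segments))
    stop_validation("'segments' needs columns 'kind' and 'duration_s'")
  if (!all(segments$kind %in% c("speech", "silence")))
    stop_validation("segment kind must be 'speech' or 'silence'")
  if (any(segments$duration_s <= 0))
    stop_validation("segment durations must be positive")
  if (segments$kind[1] != "speech" ||
      segments$kind[nrow(segments)] != "speech")
    stop_validation("segment spec must start and end with speech")
  if (is.null(segments$level_db)) segments$level_db <- -20
  segments$level_db[is.na(segments$level_db)] <- -20
  speech_min <- min(segments$level_db[segments$kind == "speech"])
  floor_db <- speech_min - floor_offset_db
  with_seed(seed, {
    pieces <- vector("list", nrow(segments))
    t0 <- cumsum(c(0, segments$duration_s))
    for (i in seq_len(nrow(segments))) {
      n <- round(segments$duration_s[i] * rate)
      lev <- if (segments$kind[i] == "speech") segments$level_db[i]
             else floor_db
      pieces[[i]] <- noise_at_db(n, lev)
    }
    x <- unlist(pieces)
    x <- pmax(-1, pmin(1, x))
    sil <- segments$kind == "silence"
    truth <- intervals(t0[which(sil)], t0[which(sil) + 1L])
    list(waveform = waveform(x, rate), truth = truth)
  })
}

#' Synthesize a two-vowel word token
#'
#' Two harmonic "vowel" segments (fundamental plus two harmonics, 5 ms
#' raised-cosine onset/offset ramps) at the requested RMS levels,
#' separated and padded by floor-level noise. The returned token carries
#' the true vowel boundaries, so PVI recovery can be checked against
#' ground truth.
#'
#' @param d1_ms,d2_ms Vowel durations in ms (> 0).
#' @param level1_db,level2_db Vowel RMS levels, dB full scale.
#' @param gap_ms Inter-vowel gap in ms (default 60).
#' @param rate Sampling rate in Hz (default 48000).
#' @param seed Optional integer seed (affects the noise floor only).
#' @param f0 Fundamental frequency in Hz (default 125).
#' @param word,pattern Token metadata; pattern defaults to `"WS"` when
#'   `d1_ms < d2_ms`, else `"SW"`.
#' @param pad_ms Floor-noise padding before/after the word (default 150).
#' @return List with `waveform` and `token` (a [word_tokens()] row).
#' @export
synth_word <- function(d1_ms, d2_ms, level1_db = -20, level2_db = -20,
                       gap_ms = 60, rate = 48000, seed = NULL, f0 = 125,
                       word = "synthetic",
                       pattern = if (d1_ms < d2_ms) "WS" else "SW",
                       pad_ms = 150) {
  if (d1_ms <= 0 || d2_ms <= 0 || gap_ms <= 0 || pad_ms <= 0)
    stop_validation("durations must be positive")
  floor_db <- min(level1_db, level2_db) - 40
  vowel <- function(d_ms, level_db) {
    n <- round(d_ms / 1000 * rate)
    t <- seq_len(n) / rate
    x <- sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t) +
      0.25 * sin(2 * pi * 3 * f0 * t)
    ramp_n <- min(round(0.005 * rate), n %/% 2)
    if (ramp_n > 0) {
      r <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
      x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * r
      x[(n - ramp_n + 1):n] <- x[(n - ramp_n + 1):n] * rev(r)
    }
    x / sqrt(mean(x^2)) * 10^(level_db / 20)
  }
  with_seed(seed, {
    pad <- noise_at_db(round(pad_ms / 1000 * rate), floor_db)
    gap <- noise_at_db(round(gap_ms / 1000 * rate), floor_db)
    v1 <- vowel(d1_ms, level1_db)
    v2 <- vowel(d2_ms, level2_db)
    x <- c(pad, v1, gap, v2, pad)
    x <- pmax(-1, pmin(1, x))
    v1_on <- length(pad) / rate
    v1_off <- v1_on + length(v1) / rate
    v2_on <- v1_off + length(gap) / rate
    v2_off <- v2_on + length(v2) / rate
    tok <- word_tokens(word, v1_on, v1_off, v2_on, v2_off, pattern)
    list(waveform = waveform(x, rate), token = tok)
  })
}
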