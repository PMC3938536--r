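#' Pairwise Variability Index
#'
#' `PVI = 100 * (d1 - d2) / ((d1 + d2) / 2)` for two positive quantities
#' (vowel durations in ms or peak intensities on a positive dB scale).
#' The mean-normalization makes the index scale-invariant, allowing
#' comparison across speaking rates and loudness levels; values close to
#' zero indicate equalized lexical stress. The signed value is
#' antisymmetric in its arguments and bounded by 200 in magnitude.
#'
#' @param d1,d2 Positive numeric vectors (first and second vowel).
#' @return A data frame with columns `signed` and `absolute`.
#' @examples
#' pvi(100, 300)  # signed -100
#' pvi(180, 120)  # signed  +40
#' @export
pvi <- function(d1, d2) {
  d1 <- as.numeric(d1); d2 <- as.numeric(d2)
  if (length(d1) != length(d2))
    stop_validation("'d1' and 'd2' differ in length")
  if (any(!is.finite(d1)) || any(!is.finite(d2)) ||
      any(d1 <= 0) || any(d2 <= 0))
    stop_validation("PVI inputs must be positive and finite")
  s <- 100 * (d1 - d2) / ((d1 + d2) / 2)
  data.frame(signed = s, absolute = abs(s))
}

# word lists with stress pattern over the first two syllables
.sw_words <- c("butterfly", "bicycle", "caterpillar", "dinosaur",
               "stethoscope")
.ws_words <- c("banana", "computer", "pagoda", "potato", "thermometer")

#' Stress pattern of a built-in stimulus word
#'
#' The ten repetition stimuli: five with a strong-weak (SW) pattern over
#' the first two syllables (butterfly, bicycle, caterpillar, dinosaur,
#' stethoscope) and five weak-strong (WS) (banana, computer, pagoda,
#' potato, thermometer). Matching is case-insensitive.
#'
#' @param word Character vector of words.
#' @return Character vector of `"SW"`, `"WS"`, or `NA` for unknown words.
#' @export
stress_pattern <- function(word) {
  w <- tolower(trimws(word))
  out <- rep(NA_character_, length(w))
  out[w %in% .sw_words] <- "SW"
  out[w %in% .ws_words] <- "WS"
  out
}

#' Construct word tokens
#'
#' A word token records the first two vowel intervals of a polysyllabic
#' word production. For the built-in stimulus words the stress pattern is
#' inferred; unknown words require an explicit `pattern`.
#'
#' @param word Character vector.
#' @param v1_on,v1_off,v2_on,v2_off Vowel onset/offset times in seconds;
#'   `v1_off <= v2_on` and both vowels must have positive duration.
#' @param pattern Optional `"SW"`/`"WS"` vector; inferred for known words.
#' @return A data frame of class `word_tokens` with columns `word`,
#'   `pattern`, `v1_on`, `v1_off`, `v2_on`, `v2_off`.
#' @export
word_tokens <- function(word, v1_on, v1_off, v2_on, v2_off, pattern = NULL) {
  n <- length(word)
  if (is.null(pattern)) pattern <- rep(NA_character_, n)
  pattern <- toupper(as.character(pattern))
  inferred <- stress_pattern(word)
  pattern[is.na(pattern) | pattern == ""] <-
    inferred[is.na(pattern) | pattern == ""]
  if (anyNA(pattern))
    stop_validation("unknown word(s) without explicit stress pattern: ",
                    paste(word[is.na(pattern)], collapse = ", "))
  if (!all(pattern %in% c("SW", "WS")))
    stop_validation("stress pattern must be 'SW' or 'WS'")
  for (nm in c("v1", "v2")) {
    on <- get(paste0(nm, "_on")); off <- get(paste0(nm, "_off"))
    bad <- which(!(off > on))
    if (length(bad))
      stop_validation("reversed or zero-length ", nm, " interval for row ",
                      paste(bad, collapse = ", "), " (word ",
                      paste(word[bad], collapse = ", "), ")")
  }
  bad <- which(v2_on < v1_off)
  if (length(bad))
    stop_validation("overlapping vowel intervals for row ",
                    paste(bad, collapse = ", "))
  structure(data.frame(word = as.character(word), pattern = pattern,
                       v1_on = v1_on, v1_off = v1_off,
                       v2_on = v2_on, v2_off = v2_off),
            class = c("word_tokens", "data.frame"))
}

#' PVI measures for word tokens
#'
#' For each token, the duration PVI from the two vowel interval lengths
#' (ms) and the intensity PVI from the peak contour value over each vowel.
#' Peak intensities are offset by `int_offset_db` (default +96, mapping
#' the dB-full-scale contour onto a positive pseudo-SPL scale) before the
#' PVI ratio, which would otherwise depend on the arbitrary dB reference
#' of an uncalibrated recording.
#'
#' @param w A [waveform()] containing the word production(s).
#' @param tokens A [word_tokens()] data frame (intervals in seconds,
#'   inside the waveform span).
#' @param window_s,hop_s Contour parameters, see [intensity_contour()].
#' @param int_offset_db Offset added to peak dB values before the
#'   intensity PVI.
#' @return A data frame with one row per token: `word`, `pattern`,
#'   `d1_ms`, `d2_ms`, `pvi_dur_signed`, `pvi_dur_abs`, `peak1_db`,
#'   `peak2_db`, `pvi_int_signed`, `pvi_int_abs`.
#' @export
word_pvi <- function(w, tokens, window_s = 0.032, hop_s = 0.008,
                     int_offset_db = 96) {
  stopifnot(inherits(w, "waveform"))
  tokens <- as.data.frame(tokens)
  dur <- wave_duration(w)
  if (nrow(tokens) && max(tokens$v2_off) > dur + 1e-9)
    stop_validation("token intervals extend past the waveform (",
                    signif(dur, 4), " s)")
  ic <- intensity_contour(w, window_s = window_s, hop_s = hop_s)
  out <- lapply(seq_len(nrow(tokens)), function(i) {
    t <- tokens[i, ]
    d1 <- (t$v1_off - t$v1_on) * 1000
    d2 <- (t$v2_off - t$v2_on) * 1000
    p1 <- peak_db(ic, t$v1_on, t$v1_off)
    p2 <- peak_db(ic, t$v2_on, t$v2_off)
    pd <- pvi(d1, d2)
    pi_ <- pvi(p1 + int_offset_db, p2 + int_offset_db)
    data.frame(word = t$word, pattern = t$pattern,
               d1_ms = d1, d2_ms = d2,
               pvi_dur_signed = pd$signed, pvi_dur_abs = pd$absolute,
               peak1_db = p1, peak2_db = p2,
               pvi_int_signed = pi_$signed, pvi_int_abs = pi_$absolute)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-subject stress profile
#'
#' Reduces word-level PVI records to the per-subject features analysed in
#' the classification models: the median PVI of duration and intensity,
#' separately for WS and SW words, in both signed and absolute variants.
#' A pattern with no tokens yields `NA` medians.
#'
#' @param records Data frame as returned by [word_pvi()] (needs columns
#'   `pattern`, `pvi_dur_signed`, `pvi_dur_abs`, `pvi_int_signed`,
#'   `pvi_int_abs`).
#' @return An object of class `stress_profile`: a one-row data frame with
#'   median PVI columns (`median_pvi_dur_ws`, `median_pvi_dur_sw`,
#'   `median_pvi_int_ws`, `median_pvi_int_sw`, plus `_signed` variants)
#'   and token counts `n_tokens_ws`, `n_tokens_sw`.
#' @export
stress_profile <- function(records) {
  records <- as.data.frame(records)
  med <- function(pattern, col) {
    v <- records[[col]][records$pattern == pattern]
    if (length(v)) stats::median(v) else NA_real_
  }
  out <- data.frame(
    median_pvi_dur_ws = med("WS", "pvi_dur_abs"),
    median_pvi_dur_sw = med("SW", "pvi_dur_abs"),
    median_pvi_int_ws = med("WS", "pvi_int_abs"),
    median_pvi_int_sw = med("SW", "pvi_int_abs"),
    median_pvi_dur_ws_signed = med("WS", "pvi_dur_signed"),
    median_pvi_dur_sw_signed = med("SW", "pvi_dur_signed"),
    median_pvi_int_ws_signed = med("WS", "pvi_int_signed"),
    median_pvi_int_sw_signed = med("SW", "pvi_int_signed"),
    n_tokens_ws = sum(records$pattern == "WS"),
    n_tokens_sw = sum(records$pattern == "SW"))
  class(out) <- c("stress_profile", "data.frame")
  out
}
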