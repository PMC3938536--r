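#' Silence-detection configuration
#'
#' Parameters of the three-criterion silence definition: frames are silent
#' when the intensity contour falls below a threshold placed
#' `threshold_frac` of the way from the minimum intensity to a reference
#' intensity (itself `ref_frac` of the way from minimum to maximum, a
#' reference more robust to irregular energy bursts than the raw maximum);
#' candidate silences shorter than `min_silence_s` are discarded; speech
#' runs shorter than `min_speech_s` between silences are absorbed.
#'
#' @param threshold_frac Fraction of the min-to-reference distance
#'   (default 0.65).
#' @param ref_frac Fraction of the min-to-max range defining the reference
#'   intensity (default 0.95).
#' @param min_silence_s Minimum silence duration in seconds (default
#'   0.015).
#' @param min_speech_s Minimum intervening speech duration in seconds
#'   (default 0.030).
#' @return An object of class `silence_config`.
#' @export
silence_config <- function(threshold_frac = 0.65, ref_frac = 0.95,
                           min_silence_s = 0.015, min_speech_s = 0.030) {
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop_validation("'threshold_frac' must be in (0, 1]")
  if (ref_frac <= 0 || ref_frac > 1)
    stop_validation("'ref_frac' must be in (0, 1]")
  if (min_silence_s <= 0 || min_speech_s <= 0)
    stop_validation("minimum durations must be positive")
  structure(list(threshold_frac = threshold_frac, ref_frac = ref_frac,
                 min_silence_s = min_silence_s, min_speech_s = min_speech_s),
            class = "silence_config")
}

#' Silence threshold of an intensity contour
#'
#' `T = I_min + threshold_frac * (I_ref - I_min)` with
#' `I_ref = I_min + ref_frac * (I_max - I_min)`. Both anchors are taken
#' from the contour's observed range, so the threshold is invariant to any
#' constant dB offset (the dB reference cancels).
#'
#' @param contour An [intensity_contour()].
#' @param cfg A [silence_config()].
#' @return Threshold in dB.
#' @export
silence_threshold <- function(contour, cfg = silence_config()) {
  stopifnot(inherits(contour, "intensity_contour"),
            inherits(cfg, "silence_config"))
  i_min <- min(contour$values)
  i_max <- max(contour$values)
  if (i_max - i_min < 1e-9)
    stop_degenerate("flat intensity contour (range ",
                    signif(i_max - i_min, 3),
                    " dB): cannot place a silence threshold")
  i_ref <- i_min + cfg$ref_frac * (i_max - i_min)
  i_min + cfg$threshold_frac * (i_ref - i_min)
}

#' Detect silences in an intensity contour
#'
#' Maximal runs of sub-threshold frames become candidate silence
#' intervals, extended by half an analysis window on each side (a frame
#' only drops below threshold once its window is almost entirely inside
#' the silence, so raw run edges bias boundaries inward). Rules are then
#' applied in a fixed order: (1) silences separated by less than
#' `min_speech_s` of speech are merged (short speech absorbed); (2)
#' silences shorter than `min_silence_s` are discarded; (3) leading and
#' trailing silences touching the sample edges are removed and define the
#' analysed span (first speech onset to last speech offset); (4) portions
#' overlapping `exclusions` (non-speech bursts such as coughs) are cut
#' out, and excluded time is also subtracted from the span used as the
#' proportion-of-silence-time denominator.
#'
#' @param contour An [intensity_contour()].
#' @param cfg A [silence_config()].
#' @param exclusions Optional data frame of intervals (`start`, `end`,
#'   seconds) to mask out.
#' @return A data frame of silence intervals (`start`, `end`) with
#'   attributes `span` (numeric length-2 analysed span), `excluded_s`
#'   (excluded time within the span) and `threshold_db`.
#' @export
detect_silences <- function(contour, cfg = silence_config(),
                            exclusions = NULL) {
  stopifnot(inherits(contour, "intensity_contour"))
  thr <- silence_threshold(contour, cfg)
  half_win <- contour$window_s / 2
  edge0 <- contour$times[1] - half_win
  edge1 <- contour$times[length(contour$times)] + half_win

  below <- contour$values < thr
  runs <- run_bounds(below)
  if (nrow(runs)) {
    sil <- data.frame(
      start = pmax(edge0, contour$times[runs$first] - half_win),
      end   = pmin(edge1, contour$times[runs$last] + half_win))
  } else {
    sil <- intervals()
  }

  # (1) absorb speech gaps shorter than min_speech_s
  sil <- merge_close(sil, cfg$min_speech_s)
  # (2) discard short silences
  if (nrow(sil)) sil <- sil[sil$end - sil$start >= cfg$min_silence_s, ,
                            drop = FALSE]
  # (3) trim edge silences; they define the analysed span
  span <- c(edge0, edge1)
  tol <- contour$hop_s / 2
  if (nrow(sil) && sil$start[1] <= edge0 + tol) {
    span[1] <- sil$end[1]
    sil <- sil[-1, , drop = FALSE]
  }
  if (nrow(sil) && sil$end[nrow(sil)] >= edge1 - tol) {
    span[2] <- sil$start[nrow(sil)]
    sil <- sil[-nrow(sil), , drop = FALSE]
  }
  # (4) exclusion mask
  excl <- as_intervals(exclusions)
  excluded_s <- 0
  if (nrow(excl)) {
    excl$start <- pmax(excl$start, span[1])
    excl$end <- pmin(excl$end, span[2])
    excl <- excl[excl$end > excl$start, , drop = FALSE]
    if (nrow(excl)) {
      excluded_s <- sum(excl$end - excl$start)
      sil <- subtract_intervals(sil, excl)
      sil <- sil[sil$end - sil$start >= cfg$min_silence_s, , drop = FALSE]
    }
  }
  rownames(sil) <- NULL
  structure(sil, span = span, excluded_s = excluded_s, threshold_db = thr)
}

# first/last indices of TRUE runs in a logical vector
run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  firsts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(first = firsts[keep], last = ends[keep])
}

# merge intervals whose gap is below min_gap (also handles overlaps)
merge_close <- function(iv, min_gap) {
  if (nrow(iv) < 2L) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  for (i in 2:nrow(iv)) {
    if (iv$start[i] - out_e[length(out_e)] < min_gap) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end[i])
    } else {
      out_s <- c(out_s, iv$start[i]); out_e <- c(out_e, iv$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

# set difference of interval lists (a minus b), both sorted, non-overlapping
subtract_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_len(nrow(a))) {
    segs_s <- a$start[i]; segs_e <- a$end[i]
    for (j in seq_len(nrow(b))) {
      new_s <- numeric(); new_e <- numeric()
      for (k in seq_along(segs_s)) {
        s <- segs_s[k]; e <- segs_e[k]
        if (b$end[j] <= s || b$start[j] >= e) {        # no overlap
          new_s <- c(new_s, s); new_e <- c(new_e, e)
        } else {
          if (b$start[j] > s) { new_s <- c(new_s, s); new_e <- c(new_e, b$start[j]) }
          if (b$end[j] < e)   { new_s <- c(new_s, b$end[j]); new_e <- c(new_e, e) }
        }
      }
      segs_s <- new_s; segs_e <- new_e
      if (!length(segs_s)) break
    }
    out_s <- c(out_s, segs_s); out_e <- c(out_e, segs_e)
  }
  data.frame(start = out_s, end = out_e)
}

#' Summarize detected silences
#'
#' Proportion of silence time (PST; summed silence duration over the
#' analysed span, minus any excluded time), its variance-stabilizing
#' arcsine transform `asin(sqrt(pst))` in radians, and the median and
#' median absolute deviation (MAD, unscaled) of the silence-duration
#' multiset. With no silences, PST is 0 and median/MAD are `NA` (undefined
#' rather than zero).
#'
#' @param silences Data frame of silence intervals, e.g. from
#'   [detect_silences()] (its `span`/`excluded_s` attributes are used when
#'   the `span` argument is missing).
#' @param span Length-2 numeric: analysed span in seconds.
#' @param excluded_s Time excluded from the denominator (seconds).
#' @return An object of class `silence_metrics`: list with `pst`,
#'   `arcsin_pst`, `median_s`, `mad_s`, `n_silences`, `span`,
#'   `excluded_s`.
#' @export
silence_metrics <- function(silences, span = attr(silences, "span"),
                            excluded_s = attr(silences, "excluded_s") %||% 0) {
  force(span); force(excluded_s)
  silences <- as_intervals(as.data.frame(silences))
  if (is.null(span) || length(span) != 2L || span[2] <= span[1])
    stop_validation("'span' must be a length-2 increasing numeric vector")
  if (nrow(silences) &&
      (min(silences$start) < span[1] - 1e-9 ||
       max(silences$end) > span[2] + 1e-9))
    stop_validation("silence intervals fall outside the analysed span")
  denom <- (span[2] - span[1]) - excluded_s
  if (denom <= 0) stop_validation("analysed span has no unexcluded time")
  durs <- silences$end - silences$start
  pst <- sum(durs) / denom
  pst <- min(max(pst, 0), 1)
  structure(list(
    pst = pst,
    arcsin_pst = asin(sqrt(pst)),
    median_s = if (length(durs)) stats::median(durs) else NA_real_,
    mad_s = if (length(durs)) stats::mad(durs, constant = 1) else NA_real_,
    n_silences = length(durs),
    span = as.numeric(span),
    excluded_s = excluded_s), class = "silence_metrics")
}

#' @export
print.silence_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<silence_metrics: pst %.3f (arcsin %.3f rad), median %s ms, ",
    "MAD %s ms, n = %d, span %.3f..%.3f s>\n"),
    x$pst, x$arcsin_pst,
    if (is.na(x$median_s)) "NA" else sprintf("%.1f", x$median_s * 1000),
    if (is.na(x$mad_s)) "NA" else sprintf("%.1f", x$mad_s * 1000),
    x$n_silences, x$span[1], x$span[2]))
  invisible(x)
}

#' @export
as.data.frame.silence_metrics <- function(x, ...) {
  data.frame(pst = x$pst, arcsin_pst = x$arcsin_pst,
             median_ms = x$median_s * 1000, mad_ms = x$mad_s * 1000,
             n_silences = x$n_silences,
             span_start_s = x$span[1], span_end_s = x$span[2])
}

#' One-call silence analysis of a recording
#'
#' Convenience wrapper: intensity contour, silence detection and summary
#' metrics in one step.
#'
#' @param w A [waveform()] or path to a WAV file.
#' @param cfg A [silence_config()].
#' @param exclusions Optional exclusion intervals (data frame or path to a
#'   CSV with columns `start_s`, `end_s`).
#' @param window_s,hop_s,floor_db Contour parameters, see
#'   [intensity_contour()].
#' @return A list with `metrics` ([silence_metrics()]), `silences` (the
#'   interval data frame) and `contour`.
#' @export
analyze_silences <- function(w, cfg = silence_config(), exclusions = NULL,
                             window_s = 0.032, hop_s = 0.008,
                             floor_db = -96) {
  if (is.character(w)) w <- read_wav(w)
  if (is.character(exclusions)) exclusions <- read_exclusions(exclusions)
  ic <- intensity_contour(w, window_s = window_s, hop_s = hop_s,
                          floor_db = floor_db)
  sil <- detect_silences(ic, cfg, exclusions)
  list(metrics = silence_metrics(sil), silences = as.data.frame(sil),
       contour = ic)
}

#' Read an exclusion-interval CSV
#'
#' @param path CSV with columns `start_s`, `end_s` (seconds).
#' @return A data frame of intervals.
#' @export
read_exclusions <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(d)))
    stop_validation("exclusion CSV needs columns 'start_s' and 'end_s': ",
                    path)
  intervals(d$start_s, d$end_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
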