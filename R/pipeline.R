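#' Pipeline configuration
#'
#' Bundles every tunable parameter of the subject-level pipeline so a run
#' is reproducible from its configuration alone.
#'
#' @param window_s,hop_s,floor_db Intensity-contour parameters.
#' @param silence A [silence_config()].
#' @param tier Annotation tier name for TextGrid input.
#' @param int_offset_db Intensity-PVI dB offset (see [word_pvi()]).
#' @param model Default index model, `"duration"` or
#'   `"silence-duration"`.
#' @param seed Integer seed for any stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 0.032, hop_s = 0.008,
                            floor_db = -96, silence = silence_config(),
                            tier = "vowels", int_offset_db = 96,
                            model = c("duration", "silence-duration"),
                            seed = 1L) {
  model <- match.arg(model)
  structure(list(window_s = window_s, hop_s = hop_s, floor_db = floor_db,
                 silence = silence, tier = tier,
                 int_offset_db = int_offset_db, model = model,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_fingerprint <- function(cfg, files = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(unclass(cfg))),
                   collapse = "\n"), tmp)
  list(parameter_hash = unname(tools::md5sum(tmp)),
       input_files = lapply(files, function(f)
         list(path = f, md5 = unname(tools::md5sum(f)))))
}

#' Run the full pipeline for one subject
#'
#' Silence metrics from the reading recording, PVI stress profile from
#' the word-repetition recording plus its vowel annotations, feature
#' assembly, and both diagnostic index models.
#'
#' @param reading_wav Path to (or [waveform()] of) the reading-passage
#'   recording.
#' @param words_wav Path to (or waveform of) the word-repetition
#'   recording.
#' @param annotations Path to the vowel annotation file (CSV or
#'   TextGrid), or a [word_tokens()] data frame.
#' @param cfg A [pipeline_config()].
#' @param subject_id Subject identifier (default `"subject"`).
#' @param exclusions Optional exclusion intervals for the reading task.
#' @param out_dir If non-`NULL`, the feature row, word-level PVI table
#'   and a JSON report are written there.
#' @return An object of class `subject_report`: list with `features`
#'   (one-row data frame in the feature schema), `words` (per-word PVI
#'   table), `profile` ([stress_profile()]), `silence`
#'   ([silence_metrics()]), `results` (per-model [duration_index()] /
#'   [silence_duration_index()] rows) and `provenance`.
#' @export
run_subject <- function(reading_wav, words_wav, annotations,
                        cfg = pipeline_config(), subject_id = "subject",
                        exclusions = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage '", name, "': ",
                                 conditionMessage(e)),
                          class = class(e)))
    })
  }
  files <- c(if (is.character(reading_wav)) reading_wav,
             if (is.character(words_wav)) words_wav,
             if (is.character(annotations)) annotations)

  sil <- stage("silences", analyze_silences(
    reading_wav, cfg$silence, exclusions,
    window_s = cfg$window_s, hop_s = cfg$hop_s, floor_db = cfg$floor_db))
  tokens <- stage("annotations", {
    if (is.character(annotations))
      read_vowel_annotations(annotations, tier = cfg$tier)
    else annotations
  })
  words <- stage("pvi", {
    w <- if (is.character(words_wav)) read_wav(words_wav) else words_wav
    word_pvi(w, tokens, window_s = cfg$window_s, hop_s = cfg$hop_s,
             int_offset_db = cfg$int_offset_db)
  })
  prof <- stress_profile(words)
  m <- sil$metrics
  features <- data.frame(
    subject_id = subject_id, group = NA_character_,
    arcsin_pst = m$arcsin_pst,
    mad_silence_s = m$mad_s, median_silence_s = m$median_s,
    pvi_dur_ws = prof$median_pvi_dur_ws,
    pvi_dur_sw = prof$median_pvi_dur_sw,
    pvi_int_ws = prof$median_pvi_int_ws,
    pvi_int_sw = prof$median_pvi_int_sw)
  results <- stage("classification", rbind(
    cbind(model = "duration",
          duration_index(features$pvi_dur_ws, features$pvi_dur_sw)),
    cbind(model = "silence-duration",
          silence_duration_index(features$arcsin_pst,
                                 features$mad_silence_s,
                                 features$pvi_dur_ws))))
  report <- structure(list(
    features = features, words = words, profile = prof,
    silence = m, results = results,
    provenance = c(config_fingerprint(cfg, files),
                   list(package_version =
                          as.character(utils::packageVersion("ppaspeech"))))),
    class = "subject_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features,
                     file.path(out_dir, paste0(subject_id, "_features.csv")),
                     row.names = FALSE)
    utils::write.csv(words,
                     file.path(out_dir, paste0(subject_id, "_words.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(features = features, results = results,
           provenance = report$provenance),
      file.path(out_dir, paste0(subject_id, "_report.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.subject_report <- function(x, ...) {
  cat("Subject:", x$features$subject_id, "\n")
  print(x$silence)
  cat(sprintf("median |PVI_dur| WS %.1f / SW %.1f (n = %d / %d tokens)\n",
              x$features$pvi_dur_ws, x$features$pvi_dur_sw,
              x$profile$n_tokens_ws, x$profile$n_tokens_sw))
  for (i in seq_len(nrow(x$results)))
    cat(sprintf("%-17s index %.3f -> %d (%s)\n", x$results$model[i],
                x$results$index[i], x$results$class_code[i],
                x$results$label[i]))
  invisible(x)
}

#' Classify (and optionally refit) a cohort
#'
#' Classifies every subject of a feature table with a
#' published-coefficient model and summarizes agreement with the labelled
#' groups; optionally screens predictors and refits the discriminant
#' function on the lvPPA/nfvPPA subjects.
#'
#' @param features Feature data frame or CSV path (schema of
#'   [read_features()]).
#' @param model `"duration"` or `"silence-duration"`.
#' @param fit If `TRUE`, run the collinearity/Mahalanobis screen and
#'   refit the discriminant function (needs both patient groups).
#' @param predictors Predictor set for the refit (default: the
#'   three-predictor silence+duration set).
#' @param alpha Mahalanobis screening alpha (default 0.001).
#' @return List with `classifications` (per-subject table), `agreement`
#'   (proportion of labelled lvPPA/nfvPPA subjects whose class matches;
#'   `NA` without labels), `by_group` counts, and when `fit = TRUE`:
#'   `screen` and `fit` (a [fit_dfa()] object).
#' @export
run_cohort <- function(features, model = c("duration", "silence-duration"),
                       fit = FALSE, predictors = c("arcsin_pst",
                                                   "mad_silence_s",
                                                   "pvi_dur_ws",
                                                   "pvi_dur_sw"),
                       alpha = 0.001) {
  model <- match.arg(model)
  if (is.character(features)) features <- read_features(features)
  cls <- classify_features(features, model)
  patients <- cls[cls$group %in% c("lvPPA", "nfvPPA"), , drop = FALSE]
  agreement <- if (nrow(patients)) {
    mean(patients$class_code == ifelse(patients$group == "nfvPPA", 1L, 0L))
  } else NA_real_
  by_group <- if (nrow(patients))
    table(group = patients$group, class = patients$label) else NULL
  out <- list(classifications = cls, agreement = agreement,
              by_group = by_group, model = model)
  if (fit) {
    if (length(unique(patients$group)) < 2L)
      stop_validation("refit requested but both patient groups ",
                      "(lvPPA, nfvPPA) are not present")
    screen <- collinearity_screen(
      patients[c(predictors,
                 intersect("median_silence_s", names(patients)))],
      cutoff = 0.80,
      priority = predictors)
    keep <- intersect(predictors, screen$retained)
    maha <- mahalanobis_screen(patients[keep], alpha = alpha)
    y <- ifelse(patients$group == "nfvPPA", 1, 0)
    out$screen <- list(collinearity = screen, mahalanobis = maha)
    out$fit <- fit_dfa(cbind(patients, .outcome = y), ".outcome", keep)
  }
  out
}
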