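#' Fit a two-group discriminant function as least-squares regression
#'
#' The discriminant function is realized, as in the reference analysis,
#' as ordinary least squares of a 0/1 group code on the screened
#' predictors (not canonical LDA; for two groups the fitted index differs
#' from Fisher's discriminant only by an affine rescaling). Standardized
#' coefficients are `beta_j = b_j * sd(x_j) / sd(y)`.
#'
#' @param data Data frame holding predictors and outcome.
#' @param outcome Name of the 0/1 outcome column, or a numeric vector.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `dfa_fit`: list with `coefficients` (data
#'   frame: `predictor`, `b`, `se`, `beta`, `t`, `p`), `constant`, `r2`,
#'   `F`, `df`, `n`, and the underlying `lm` fit.
#' @export
fit_dfa <- function(data, outcome, predictors) {
  data <- as.data.frame(data)
  y <- if (is.character(outcome) && length(outcome) == 1L) {
    if (!outcome %in% names(data))
      stop_validation("outcome column '", outcome, "' not found")
    data[[outcome]]
  } else as.numeric(outcome)
  if (!all(predictors %in% names(data)))
    stop_validation("missing predictor column(s): ",
                    paste(setdiff(predictors, names(data)), collapse = ", "))
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_validation("outcome must be coded 0/1 with no missing values")
  X <- data[predictors]
  n <- length(y)
  if (n <= length(predictors) + 1L)
    stop_validation("need n > number of predictors + 1")
  df_fit <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = df_fit)
  if (any(is.na(stats::coef(fit))))
    stop_degenerate("rank-deficient predictor matrix")
  sm <- summary(fit)
  ct <- sm$coefficients
  sdy <- stats::sd(y)
  b <- ct[-1, 1]
  beta <- b * vapply(X, stats::sd, 1) / sdy
  coefs <- data.frame(predictor = predictors,
                      b = unname(b), se = unname(ct[-1, 2]),
                      beta = unname(beta), t = unname(ct[-1, 3]),
                      p = unname(ct[-1, 4]), row.names = NULL)
  structure(list(coefficients = coefs,
                 constant = unname(ct[1, 1]),
                 constant_se = unname(ct[1, 2]),
                 r2 = sm$r.squared,
                 F = unname(sm$fstatistic[1]),
                 df = unname(sm$fstatistic[2:3]),
                 n = n, lm = fit),
            class = "dfa_fit")
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf("Discriminant function (OLS on 0/1 group code), n = %d\n",
              x$n))
  cat(sprintf("F(%d, %d) = %.3f, r^2 = %.3f\n", x$df[1], x$df[2], x$F,
              x$r2))
  cat(sprintf("(Constant)  b = %.3f (se %.3f)\n", x$constant,
              x$constant_se))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

# round half away from zero, then clamp to {0, 1}
round_half_away <- function(x) {
  r <- ifelse(x >= 0, floor(x + 0.5), ceiling(x - 0.5))
  pmin(pmax(r, 0), 1)
}

diagnostic_result <- function(index) {
  cls <- as.integer(round_half_away(index))
  data.frame(index = index, class_code = cls,
             label = ifelse(cls == 1L, "nfvPPA", "lvPPA"))
}

#' Duration index (published two-predictor model)
#'
#' Continuous diagnostic index from the published coefficients of the
#' two-predictor model:
#' `index = 1.763 - 0.008 * |PVI_Duration_WS| - 0.007 * |PVI_Duration_SW|`.
#' Rounded to zero decimals (half away from zero, clamped) it codes
#' 0 = lvPPA, 1 = nfvPPA. Lower absolute PVIs (more equalized lexical
#' stress, the apraxic pattern) push the index toward 1, so the index is
#' monotone non-increasing in both arguments.
#'
#' @param pvi_dur_ws_abs,pvi_dur_sw_abs Absolute median duration PVIs for
#'   weak-strong and strong-weak words (>= 0).
#' @param coef Named numeric: `constant`, `ws`, `sw` (defaults are the
#'   published values).
#' @return A data frame with `index`, `class_code`, `label`.
#' @examples
#' duration_index(116.2, 89.6)  # lvPPA group medians -> class 0
#' duration_index(87.4, 63.9)   # nfvPPA group medians -> class 1
#' @export
duration_index <- function(pvi_dur_ws_abs, pvi_dur_sw_abs,
                           coef = c(constant = 1.763, ws = -0.008,
                                    sw = -0.007)) {
  if (any(pvi_dur_ws_abs < 0, na.rm = TRUE) ||
      any(pvi_dur_sw_abs < 0, na.rm = TRUE))
    stop_validation("duration_index expects absolute (non-negative) PVIs")
  idx <- coef[["constant"]] + coef[["ws"]] * pvi_dur_ws_abs +
    coef[["sw"]] * pvi_dur_sw_abs
  diagnostic_result(idx)
}

#' Silence + duration index (published three-predictor model)
#'
#' `index = 2.387 - 2.057 * arcsin_pst + 2.991 * mad_silence_s
#'  - 0.010 * |PVI_Duration_WS|`, rounded/clamped to 0 (lvPPA) or
#' 1 (nfvPPA). The silence-variability predictor enters in seconds. The
#' published table prints the PVI coefficient as +0.010 while its
#' standardized coefficient and t statistic are negative; the negative
#' sign is used here (it also reproduces the published group-level
#' classifications) and can be overridden via `coef`.
#'
#' @param arcsin_pst Arcsine-transformed proportion of silence time,
#'   radians in `[0, pi/2]`.
#' @param mad_silence_s Variability (MAD) of silence duration in seconds.
#' @param pvi_dur_ws_abs Absolute median duration PVI, weak-strong words.
#' @param coef Named numeric: `constant`, `pst`, `mad`, `ws`.
#' @return A data frame with `index`, `class_code`, `label`.
#' @export
silence_duration_index <- function(arcsin_pst, mad_silence_s,
                                   pvi_dur_ws_abs,
                                   coef = c(constant = 2.387, pst = -2.057,
                                            mad = 2.991, ws = -0.010)) {
  if (any(arcsin_pst < 0 | arcsin_pst > pi / 2, na.rm = TRUE))
    stop_validation("'arcsin_pst' must lie in [0, pi/2] radians")
  if (any(pvi_dur_ws_abs < 0, na.rm = TRUE))
    stop_validation("expects absolute (non-negative) PVI")
  if (any(mad_silence_s > 5, na.rm = TRUE))
    warning("mad_silence_s > 5 s: did you pass milliseconds? ",
            "The model consumes seconds.")
  idx <- coef[["constant"]] + coef[["pst"]] * arcsin_pst +
    coef[["mad"]] * mad_silence_s + coef[["ws"]] * pvi_dur_ws_abs
  diagnostic_result(idx)
}

# canonical feature-table schema shared by simulator, pipeline and models
.feature_cols <- c("subject_id", "group", "arcsin_pst", "mad_silence_s",
                   "median_silence_s", "pvi_dur_ws", "pvi_dur_sw",
                   "pvi_int_ws", "pvi_int_sw")

#' Read a per-subject feature table
#'
#' CSV with columns `subject_id, group, arcsin_pst, mad_silence_s,
#' median_silence_s, pvi_dur_ws, pvi_dur_sw, pvi_int_ws, pvi_int_sw`
#' (duration PVIs as absolute values; silence durations in seconds).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.feature_cols, names(d))
  if (length(missing))
    stop_validation("feature CSV is missing column(s): ",
                    paste(missing, collapse = ", "))
  d
}

#' Classify subjects with a published-coefficient model
#'
#' @param features Feature data frame (schema of [read_features()]).
#' @param model `"duration"` (two-predictor) or `"silence-duration"`
#'   (three-predictor).
#' @return `features` with `index`, `class_code` and `label` columns
#'   appended.
#' @export
classify_features <- function(features,
                              model = c("duration", "silence-duration")) {
  model <- match.arg(model)
  features <- as.data.frame(features)
  res <- if (model == "duration") {
    duration_index(features$pvi_dur_ws, features$pvi_dur_sw)
  } else {
    silence_duration_index(features$arcsin_pst, features$mad_silence_s,
                           features$pvi_dur_ws)
  }
  cbind(features, res)
}
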