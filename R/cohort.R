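#' Reference group statistics for the PPA cohorts
#'
#' Per-group sample sizes and feature means/SDs from the published
#' comparison of lvPPA, nfvPPA and healthy control speakers, used as the
#' simulator defaults and as the printed-value inputs of the acceptance
#' checks. Silence durations are in seconds, the proportion of silence
#' time is arcsine-transformed (radians), and the duration PVIs are on
#' the signed scale (WS medians are negative: the second, stressed vowel
#' is longer). Intensity-PVI statistics were not published (the measure
#' did not differentiate the groups); the defaults here are a plausible
#' non-discriminative choice (signed -4/+4, SD 2.5, identical across
#' groups).
#'
#' @return Named list (`lvPPA`, `nfvPPA`, `control`), each with `n` and a
#'   data frame `features` with columns `feature`, `mean`, `sd`.
#' @export
reference_group_stats <- function() {
  feat <- function(mean, sd) data.frame(
    feature = c("arcsin_pst", "median_silence_s", "mad_silence_s",
                "pvi_dur_ws", "pvi_dur_sw", "pvi_int_ws", "pvi_int_sw"),
    mean = mean, sd = sd)
  list(
    lvPPA = list(n = 21L, features = feat(
      mean = c(0.61, 0.1259, 0.0865, -116.2, 89.6, -4.0, 4.0),
      sd   = c(0.13, 0.0500, 0.0477,   18.3, 17.0,  2.5, 2.5))),
    nfvPPA = list(n = 20L, features = feat(
      mean = c(0.62, 0.2361, 0.1586,  -87.4, 63.9, -4.0, 4.0),
      sd   = c(0.17, 0.2088, 0.1259,   26.9, 26.2,  2.5, 2.5))),
    control = list(n = 17L, features = feat(
      mean = c(0.48, 0.0833, 0.0497, -109.7, 80.7, -4.0, 4.0),
      sd   = c(0.09, 0.0272, 0.0276,   18.9, 16.0,  2.5, 2.5))))
}

#' Cohort simulation specification
#'
#' @param groups Named list as returned by [reference_group_stats()]
#'   (each element: `n` and a `features` data frame with `feature`,
#'   `mean`, `sd`). Defaults to the reference statistics.
#' @param correlation Optional feature-by-feature correlation matrix
#'   (dimnames matching the feature names), shared across groups;
#'   `NULL` (the default) means independent features.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = reference_group_stats(),
                        correlation = NULL, seed = 1L) {
  if (!length(groups) || is.null(names(groups)))
    stop_validation("'groups' must be a named list")
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (!is.numeric(gr$n) || gr$n < 1)
      stop_validation("group '", g, "': n must be >= 1")
    f <- gr$features
    if (!all(c("feature", "mean", "sd") %in% names(f)))
      stop_validation("group '", g,
                      "': features needs columns feature, mean, sd")
    if (any(f$sd < 0))
      stop_validation("group '", g, "': SDs must be >= 0")
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!isSymmetric(unname(correlation)) ||
        any(eigen(correlation, symmetric = TRUE,
                  only.values = TRUE)$values < -1e-8))
      stop_validation("'correlation' must be symmetric positive ",
                      "semi-definite")
  }
  structure(list(groups = groups, correlation = correlation,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Simulate a subject cohort
#'
#' Draws per-group feature vectors from (multivariate) normal
#' distributions with the spec's means and SDs; independent features by
#' default, or correlated via the spec's correlation matrix (applied
#' through its Cholesky factor). Duration-PVI features are sampled on the
#' signed scale and emitted as absolute values (the convention consumed
#' by the classification models); the arcsine-transformed proportion of
#' silence time is clamped to `[0, pi/2]` and silence durations to
#' non-negative values. Deterministic under the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return Data frame in the feature-table schema (see
#'   [read_features()]).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  with_seed(seed, {
    rows <- lapply(names(spec$groups), function(g) {
      gr <- spec$groups[[g]]
      f <- gr$features
      n <- gr$n
      k <- nrow(f)
      z <- matrix(stats::rnorm(n * k), n, k)
      if (!is.null(spec$correlation)) {
        R <- spec$correlation[f$feature, f$feature]
        # PSD-safe Cholesky via eigen decomposition
        e <- eigen(R, symmetric = TRUE)
        L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
        z <- z %*% t(L)
      }
      x <- sweep(sweep(z, 2, f$sd, `*`), 2, f$mean, `+`)
      colnames(x) <- f$feature
      d <- as.data.frame(x)
      d$arcsin_pst <- pmin(pmax(d$arcsin_pst, 0), pi / 2)
      d$median_silence_s <- pmax(d$median_silence_s, 0)
      d$mad_silence_s <- pmax(d$mad_silence_s, 0)
      for (col in c("pvi_dur_ws", "pvi_dur_sw", "pvi_int_ws",
                    "pvi_int_sw"))
        d[[col]] <- abs(d[[col]])
      cbind(data.frame(subject_id = sprintf("%s_%03d", g, seq_len(n)),
                       group = g), d)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[.feature_cols]
  })
}
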