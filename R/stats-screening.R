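#' Multicollinearity screen
#'
#' Pearson correlations among candidate predictors; for every pair with
#' `|r|` above the cutoff (0.80 by default), one member is excluded. The
#' `priority` argument ranks predictors by preference to retain: in a
#' flagged pair the lower-priority member is dropped (predictors not
#' listed rank below all listed ones). In the reference analysis, median
#' silence duration and its variability were correlated above 0.80 and
#' the median was dropped in favour of the variability measure.
#'
#' @param x Data frame or matrix of numeric predictors (columns named).
#' @param cutoff Absolute correlation above which a pair is flagged
#'   (default 0.80).
#' @param priority Character vector of predictor names, most preferred
#'   first.
#' @return List with `correlations` (matrix), `retained`, `excluded`
#'   (character vectors) and `flagged_pairs` (data frame).
#' @export
collinearity_screen <- function(x, cutoff = 0.80, priority = NULL) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  x <- x[num]
  if (ncol(x) < 2L) stop_validation("need at least 2 numeric predictors")
  if (nrow(x) < 3L) stop_validation("need at least 3 subjects")
  sds <- vapply(x, stats::sd, 1)
  if (any(sds == 0))
    stop_degenerate("constant predictor(s): ",
                    paste(names(x)[sds == 0], collapse = ", "))
  cm <- stats::cor(as.matrix(x))
  rank_of <- function(nm) {
    r <- match(nm, priority)
    ifelse(is.na(r), length(priority) + match(nm, colnames(cm)), r)
  }
  flagged <- which(abs(cm) > cutoff & upper.tri(cm), arr.ind = TRUE)
  excluded <- character()
  pairs <- NULL
  if (nrow(flagged)) {
    pairs <- data.frame(
      var1 = colnames(cm)[flagged[, 1]],
      var2 = colnames(cm)[flagged[, 2]],
      r = cm[flagged])
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$var1[i]; b <- pairs$var2[i]
      if (a %in% excluded || b %in% excluded) next
      drop <- if (rank_of(a) <= rank_of(b)) b else a
      excluded <- c(excluded, drop)
    }
  }
  list(correlations = cm,
       retained = setdiff(colnames(cm), excluded),
       excluded = excluded,
       flagged_pairs = pairs)
}

#' Chi-square critical value
#'
#' Upper-tail critical value of the chi-square distribution, used as the
#' cutoff for Mahalanobis outlier screening (with `df` equal to the
#' number of predictors; df 4 at alpha 0.001 gives 18.47).
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Upper-tail probability in (0, 1).
#' @return Critical value `c` with `P(X > c) = alpha`.
#' @examples
#' round(chi2_critical(4, 0.001), 2)  # 18.47
#' @export
chi2_critical <- function(df, alpha) {
  if (any(df < 1)) stop_validation("'df' must be >= 1")
  if (any(alpha <= 0 | alpha >= 1))
    stop_validation("'alpha' must be in (0, 1)")
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Mahalanobis multivariate-outlier screen
#'
#' Squared Mahalanobis distance of each subject from the sample centroid,
#' `D2_i = (x_i - xbar)' S^-1 (x_i - xbar)` with the (n-1)-denominator
#' sample covariance `S`. Subjects whose `D2` exceeds
#' [chi2_critical()]`(p, alpha)` are flagged as multivariate outliers.
#' Note the algebraic identity `sum(D2) = p * (n - 1)` for any dataset.
#'
#' @param x Data frame or matrix of numeric predictors.
#' @param alpha Upper-tail probability for the cutoff (default 0.001).
#' @return Data frame with `d2` and `outlier` per row, plus attributes
#'   `critical` and `df`.
#' @export
mahalanobis_screen <- function(x, alpha = 0.001) {
  x <- as.matrix(as.data.frame(x))
  if (!is.numeric(x)) stop_validation("predictors must be numeric")
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1) stop_validation("need n > p + 1 (n = ", n, ", p = ", p, ")")
  S <- stats::cov(x)
  if (abs(det(S)) < 1e-12 * prod(pmax(diag(S), 1e-12)))
    stop_degenerate("singular sample covariance")
  d2 <- stats::mahalanobis(x, colMeans(x), S)
  crit <- chi2_critical(p, alpha)
  structure(data.frame(d2 = d2, outlier = d2 > crit),
            critical = crit, df = p)
}
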