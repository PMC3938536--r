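#' Skewness and kurtosis screen
#'
#' Adjusted (bias-corrected) sample skewness and excess kurtosis, the
#' formulas used by SPSS and most statistical packages:
#' `G1 = n / ((n-1)(n-2)) * sum(z^3)` and
#' `G2 = n(n+1) / ((n-1)(n-2)(n-3)) * sum(z^4) - 3(n-1)^2 / ((n-2)(n-3))`
#' with `z = (x - mean) / s`, `s` the (n-1)-denominator standard
#' deviation. Used to decide between parametric and nonparametric
#' univariate comparisons.
#'
#' @param x Numeric vector, `n >= 3` (`n >= 4` for kurtosis).
#' @return List with `skewness` and `kurtosis` (excess).
#' @export
moment_screen <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop_validation("need at least 3 observations, got ", n)
  s <- stats::sd(x)
  if (s == 0) stop_degenerate("zero variance: moments undefined")
  z <- (x - mean(x)) / s
  g1 <- n / ((n - 1) * (n - 2)) * sum(z^3)
  g2 <- if (n >= 4) {
    n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
  } else NA_real_
  list(skewness = g1, kurtosis = g2)
}

check_groups <- function(groups, min_n = 2L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_validation("'groups' must be a list of >= 2 numeric vectors")
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  n <- vapply(groups, length, 1L)
  if (any(n < min_n))
    stop_validation("every group needs at least ", min_n,
                    " observations (got ", paste(n, collapse = ", "), ")")
  groups
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA across `k` independent groups.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `F`, `df_between`, `df_within`, `p`, `ms_between`,
#'   `ms_within`.
#' @examples
#' anova_oneway(list(c(1, 2), c(3, 4)))$F  # 8
#' @export
anova_oneway <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  means <- vapply(groups, mean, 1)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- k - 1L; dfw <- N - k
  if (dfw <= 0) stop_validation("no within-group degrees of freedom")
  msw <- ssw / dfw
  if (msw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else if (msw == 0) {
    stop_degenerate("zero within-group variance with distinct means")
  } else {
    f <- (ssb / dfb) / msw
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  list(F = f, df_between = dfb, df_within = dfw, p = p,
       ms_between = ssb / dfb, ms_within = msw)
}

#' Tukey-HSD/Kramer post-hoc comparisons
#'
#' All pairwise group comparisons by the studentized range statistic,
#' with Kramer's unequal-n correction:
#' `q = |m_i - m_j| / sqrt(MSW / 2 * (1/n_i + 1/n_j))`; p-values from the
#' studentized range distribution with `k` groups and the ANOVA
#' within-group degrees of freedom. With equal n the Kramer term reduces
#' to the classic Tukey HSD.
#'
#' @param groups List of numeric vectors; names are used as group labels.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `se`, `q`, `p`, `significant`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  k <- length(groups)
  labs <- names(groups) %||% paste0("g", seq_len(k))
  labs[labs == ""] <- paste0("g", which(labs == ""))
  av <- anova_oneway(groups)
  n <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(av$ms_within / 2 * (1 / n[i] + 1 / n[j]))
    d <- means[i] - means[j]
    q <- if (se == 0) 0 else abs(d) / se
    p <- stats::ptukey(q, k, av$df_within, lower.tail = FALSE)
    data.frame(group1 = labs[i], group2 = labs[j], diff = d, se = se,
               q = q, p = p, significant = p < alpha)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Independent-samples median test
#'
#' Classifies every observation as above or not-above the pooled median
#' and tests independence of the group-by-side contingency table: a
#' chi-square test when all expected counts are at least 5, otherwise
#' Fisher's exact test.
#'
#' @param groups List of numeric vectors.
#' @return List with `p`, `method` (`"chi-square"` or `"exact"`),
#'   `statistic` (chi-square value or `NA`), `counts` (2 x k table) and
#'   `pooled_median`.
#' @export
median_test <- function(groups) {
  groups <- check_groups(groups, min_n = 1L)
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    stop_degenerate("all values identical: median test undefined")
  m <- stats::median(pooled)
  counts <- vapply(groups, function(g) c(above = sum(g > m),
                                         not_above = sum(g <= m)),
                   numeric(2))
  exp_counts <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(exp_counts < 5)) {
    p <- stats::fisher.test(counts)$p.value
    list(p = p, method = "exact", statistic = NA_real_, counts = counts,
         pooled_median = m)
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(p = ct$p.value, method = "chi-square",
         statistic = unname(ct$statistic), counts = counts,
         pooled_median = m)
  }
}
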