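test_that("moment screen pins the adjusted formulas", {
  expect_equal(moment_screen(c(-1, 0, 1))$skewness, 0)
  expect_gt(moment_screen(c(0, 0, 0, 10))$skewness, 0)
  # independent hand computation for {1..5}: G2 = 1.25 * 5.44 - 8 = -1.2
  expect_equal(moment_screen(1:5)$kurtosis, -1.2)
  expect_error(moment_screen(rep(2, 5)), "zero variance",
               class = "ppa_degenerate_error")
  expect_error(moment_screen(c(1, 2)), "at least 3",
               class = "ppa_validation_error")
})

test_that("one-way ANOVA matches hand computation and is order-invariant", {
  id <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(id$F, 0)
  expect_equal(id$p, 1)

  av <- anova_oneway(list(c(1, 2), c(3, 4)))
  expect_equal(av$F, 8)          # MSB 4 / MSW 0.5
  expect_equal(av$df_between, 1)
  expect_equal(av$df_within, 2)

  g3 <- list(a = c(1, 2, 3), b = c(2, 3, 5), c = c(9, 10, 12))
  expect_equal(anova_oneway(g3)$F, anova_oneway(rev(g3))$F)
  expect_error(anova_oneway(list(1, 2)), "at least 2",
               class = "ppa_validation_error")
})

test_that("ANOVA F agrees with the lm/aov reference on random data", {
  set.seed(51)
  for (i in 1:5) {
    g <- lapply(sample(3:5, 3, TRUE), function(n) rnorm(n, sd = 2))
    av <- anova_oneway(g)
    y <- unlist(g)
    f <- factor(rep(seq_along(g), lengths(g)))
    ref <- anova(stats::lm(y ~ f))
    expect_equal(av$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(av$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("Tukey-Kramer flags separated pairs, reduces to HSD at equal n", {
  two <- tukey_kramer(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(two$q, 0)
  expect_false(two$significant)

  g <- list(a = c(1.0, 1.2, 0.9, 1.1), b = c(1.3, 1.1, 1.2, 1.4),
            c = c(9.8, 10.1, 10.0, 9.9))
  tk <- tukey_kramer(g)
  far <- tk$group2 == "c" | tk$group1 == "c"
  expect_true(all(tk$significant[far]))
  expect_false(any(tk$significant[!far]))

  # equal-n: p-values match TukeyHSD on the same data
  y <- unlist(g); f <- factor(rep(names(g), lengths(g)))
  ref <- stats::TukeyHSD(stats::aov(y ~ f))$f
  ref_p <- ref[order(rownames(ref)), "p adj"]
  ours <- tk$p[order(paste(tk$group2, tk$group1, sep = "-"))]
  expect_equal(unname(ours), unname(ref_p), tolerance = 1e-6)

  # unequal n: q uses the Kramer term
  gu <- list(a = c(1, 2), b = c(1.5, 2.5, 3.5), c = c(9, 10, 11, 12))
  tku <- tukey_kramer(gu)
  av <- anova_oneway(gu)
  se_ab <- sqrt(av$ms_within / 2 * (1 / 2 + 1 / 3))
  expect_equal(tku$q[tku$group1 == "a" & tku$group2 == "b"],
               abs(mean(gu$a) - mean(gu$b)) / se_ab)
})

test_that("median test matches the enumeration oracle on tiny groups", {
  r <- median_test(list(c(1, 3), c(2, 4)))
  expect_equal(unname(r$counts["above", ]), c(1, 1))
  expect_equal(r$method, "exact")
  expect_equal(r$p, 1)
  expect_equal(r$p, median_test_exact_oracle(c(1, 3), c(2, 4)))

  sep <- median_test(list(c(1, 2), c(9, 10)))
  expect_equal(sep$p, median_test_exact_oracle(c(1, 2), c(9, 10)))
  expect_equal(sep$p, 1 / 3)     # smallest attainable p at n = 4

  # permutation within groups changes nothing
  expect_equal(median_test(list(c(3, 1), c(4, 2)))$p, r$p)
  expect_error(median_test(list(c(2, 2), c(2, 2))), "identical",
               class = "ppa_degenerate_error")

  # large balanced case switches to chi-square
  set.seed(52)
  big <- median_test(list(rnorm(40), rnorm(40, 2)))
  expect_equal(big$method, "chi-square")
  expect_lt(big$p, 0.001)
})

test_that("collinearity screen drops by priority", {
  set.seed(53)
  x <- data.frame(a = rnorm(50))
  x$b <- x$a + rnorm(50, sd = 0.01)   # duplicate-ish
  x$c <- rnorm(50)
  sc <- collinearity_screen(x, priority = c("a", "c", "b"))
  expect_equal(sc$excluded, "b")
  expect_setequal(sc$retained, c("a", "c"))
  expect_gt(abs(sc$correlations["a", "b"]), 0.99)

  # reversed priority drops the other member
  sc2 <- collinearity_screen(x, priority = c("b", "c", "a"))
  expect_equal(sc2$excluded, "a")

  expect_error(collinearity_screen(data.frame(a = rnorm(10), b = 1)),
               "constant", class = "ppa_degenerate_error")
})

test_that("independent predictors survive the screen (property, 20 seeds)", {
  n_excluded <- vapply(1:20, function(s) {
    set.seed(s)
    x <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
    length(collinearity_screen(x)$excluded)
  }, 1L)
  expect_true(all(n_excluded == 0))
})

test_that("correlated silence median and MAD reproduce the screening path", {
  # shared latent slowing induces r > 0.80 between the two silence
  # duration summaries, as in the reference cohort
  R <- diag(7)
  fn <- reference_group_stats()$lvPPA$features$feature
  dimnames(R) <- list(fn, fn)
  R["median_silence_s", "mad_silence_s"] <-
    R["mad_silence_s", "median_silence_s"] <- 0.9
  spec <- cohort_spec(correlation = R, seed = 54)
  co <- simulate_cohort(spec)
  pat <- co[co$group != "control", ]
  sc <- collinearity_screen(
    pat[c("arcsin_pst", "mad_silence_s", "median_silence_s",
          "pvi_dur_ws", "pvi_dur_sw")],
    priority = c("arcsin_pst", "mad_silence_s", "pvi_dur_ws",
                 "pvi_dur_sw"))
  expect_gt(abs(sc$correlations["median_silence_s", "mad_silence_s"]),
            0.80)
  expect_true("median_silence_s" %in% sc$excluded)
  expect_true("mad_silence_s" %in% sc$retained)
})

test_that("Mahalanobis screen: hand case, sum identity, planted outlier", {
  # 1-D hand case: x = {0, 2}, S = 2 -> D2 = 0.5 for both points
  # (computed directly; the screen itself requires n > p + 1)
  m1 <- stats::mahalanobis(matrix(c(0, 2)), 1, matrix(2))
  expect_equal(unname(m1), c(0.5, 0.5))
  expect_error(mahalanobis_screen(data.frame(x = c(0, 2))),
               "n > p", class = "ppa_validation_error")

  set.seed(55)
  x <- as.data.frame(matrix(rnorm(40 * 4), 40, 4))
  scr <- mahalanobis_screen(x)
  expect_equal(sum(scr$d2), 4 * (40 - 1))
  expect_equal(attr(scr, "critical"), chi2_critical(4, 0.001))

  x[7, ] <- 10   # ~10-sigma multivariate outlier
  scr2 <- mahalanobis_screen(x)
  expect_true(scr2$outlier[7])
  expect_false(any(scr2$outlier[-7]))
  expect_equal(sum(scr2$d2), 4 * (40 - 1))   # identity holds regardless
})

test_that("chi-square critical values and monotonicity", {
  expect_equal(round(chi2_critical(4, 0.001), 2), 18.47)
  expect_equal(chi2_critical(1, 0.05), 3.841, tolerance = 1e-3)
  expect_equal(chi2_critical(2, 0.5), log(4))   # median of Exp(1/2)
  # strictly increasing in df, decreasing in alpha
  dfs <- chi2_critical(1:10, 0.05)
  expect_true(all(diff(dfs) > 0))
  alphas <- vapply(c(0.2, 0.1, 0.05, 0.01), chi2_critical, 1, df = 3)
  expect_true(all(diff(alphas) > 0))
  expect_error(chi2_critical(0, 0.05), "df", class = "ppa_validation_error")
})

test_that("fit_dfa: hand example, OLS identities, oracle agreement", {
  d <- data.frame(y = c(0, 0, 1, 1), x = 1:4)
  f <- fit_dfa(d, "y", "x")
  expect_equal(f$coefficients$b, 0.4)
  expect_equal(f$constant, -0.5)
  expect_equal(f$r2, 0.8)

  # adding a constant to a predictor shifts only the intercept
  d2 <- transform(d, x = x + 100)
  f2 <- fit_dfa(d2, "y", "x")
  expect_equal(f2$coefficients$b, f$coefficients$b)
  expect_equal(f2$constant, f$constant - 0.4 * 100)

  # r2 equals squared correlation of fitted vs observed
  set.seed(56)
  dd <- data.frame(y = rep(c(0, 1), each = 10),
                   a = rnorm(20), b = rnorm(20))
  fd <- fit_dfa(dd, "y", c("a", "b"))
  expect_equal(fd$r2, cor(fitted(fd$lm), dd$y)^2)

  # normal-equations oracle to 1e-8 across random instances, n <= 50
  for (s in 1:10) {
    set.seed(s)
    n <- sample(8:50, 1)
    dat <- data.frame(y = rbinom(n, 1, 0.5), a = rnorm(n), b = rnorm(n),
                      c = rnorm(n))
    if (length(unique(dat$y)) < 2) next
    ff <- fit_dfa(dat, "y", c("a", "b", "c"))
    oracle <- ols_oracle(dat[c("a", "b", "c")], dat$y)
    expect_equal(unname(c(ff$constant, ff$coefficients$b)),
                 unname(oracle), tolerance = 1e-8)
  }

  # standardized coefficients: beta = b * sd(x) / sd(y)
  expect_equal(fd$coefficients$beta,
               fd$coefficients$b * c(sd(dd$a), sd(dd$b)) / sd(dd$y))

  expect_error(fit_dfa(data.frame(y = c(0, 1, 2), x = 1:3), "y", "x"),
               "0/1", class = "ppa_validation_error")
  dup <- data.frame(y = rep(c(0, 1), 5), a = 1:10, b = 1:10)
  expect_error(fit_dfa(dup, "y", c("a", "b")), "rank",
               class = "ppa_degenerate_error")
})

test_that("published-coefficient indices reproduce the derived examples", {
  # two-predictor model on the group-median features
  lv <- duration_index(116.2, 89.6)
  expect_equal(lv$index, 0.2062)
  expect_equal(lv$class_code, 0L)
  expect_equal(lv$label, "lvPPA")

  nf <- duration_index(87.4, 63.9)
  expect_equal(nf$index, 0.6165)
  expect_equal(nf$class_code, 1L)
  expect_equal(nf$label, "nfvPPA")

  zero <- duration_index(0, 0)
  expect_equal(zero$index, 1.763)
  expect_equal(zero$class_code, 1L)

  # three-predictor model
  lv1 <- silence_duration_index(0.61, 0.0865, 116.2)
  expect_equal(lv1$index, 0.2289515, tolerance = 1e-6)
  expect_equal(lv1$class_code, 0L)
  nf1 <- silence_duration_index(0.62, 0.1586, 87.4)
  expect_equal(nf1$index, 0.7120326, tolerance = 1e-6)
  expect_equal(nf1$class_code, 1L)
  expect_equal(silence_duration_index(0, 0, 0)$index, 2.387)
  expect_equal(silence_duration_index(0, 0, 0)$class_code, 1L)

  expect_error(duration_index(-5, 10), "absolute",
               class = "ppa_validation_error")
  expect_warning(silence_duration_index(0.6, 86.5, 100), "seconds")
})

test_that("duration index is monotone non-increasing in each PVI", {
  set.seed(57)
  w <- runif(50, 0, 150); s <- runif(50, 0, 150); eps <- runif(50, 0, 20)
  expect_true(all(duration_index(w + eps, s)$index <=
                    duration_index(w, s)$index))
  expect_true(all(duration_index(w, s + eps)$index <=
                    duration_index(w, s)$index))
})

test_that("rounding is half-away-from-zero with clamping", {
  expect_equal(duration_index(0, 0, c(constant = 0.5, ws = 0, sw = 0))$class_code, 1L)
  expect_equal(duration_index(0, 0, c(constant = -0.2, ws = 0, sw = 0))$class_code, 0L)
  expect_equal(duration_index(0, 0, c(constant = 2.9, ws = 0, sw = 0))$class_code, 1L)
  expect_equal(duration_index(0, 0, c(constant = 0.49, ws = 0, sw = 0))$class_code, 0L)
})
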