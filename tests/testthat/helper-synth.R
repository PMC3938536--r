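# Shared fixtures and independent oracles. Audio fixtures are generated at
# test time (16 kHz keeps the suite fast; nothing in the measures depends
# on the rate once a full analysis window fits).

test_rate <- 16000

# alternating speech/silence spec from a vector of silence durations
speech_sandwich <- function(silences_s, speech_s = 0.4, level_db = -20) {
  n <- length(silences_s)
  kind <- c("speech", rbind(rep("silence", n), rep("speech", n)))
  dur <- c(speech_s, rbind(silences_s, rep(speech_s, n)))
  data.frame(kind = kind, duration_s = as.numeric(dur),
             level_db = level_db)
}

# independent OLS oracle: normal equations, no lm()
ols_oracle <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}

# enumeration oracle for the 2x2 exact median test: hypergeometric
# probabilities of all tables with the observed margins
median_test_exact_oracle <- function(g1, g2) {
  pooled <- c(g1, g2)
  m <- median(pooled)
  a <- sum(g1 > m); b <- sum(g2 > m)
  n1 <- length(g1); n2 <- length(g2); k <- a + b
  probs <- vapply(max(0, k - n2):min(n1, k), function(x)
    choose(n1, x) * choose(n2, k - x) / choose(n1 + n2, k), 1)
  obs <- choose(n1, a) * choose(n2, b) / choose(n1 + n2, k)
  sum(probs[probs <= obs + 1e-12])
}

ref_medians <- function(group) {
  f <- reference_group_stats()[[group]]$features
  stats::setNames(f$mean, f$feature)
}
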