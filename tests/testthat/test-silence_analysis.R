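make_contour <- function(values, hop = 0.008, window = 0.032) {
  structure(list(times = window / 2 + hop * (seq_along(values) - 1),
                 values = values, window_s = window, hop_s = hop,
                 floor_db = -96), class = "intensity_contour")
}

test_that("silence threshold follows the range-relative formula", {
  ic <- make_contour(c(0, 25, 50, 75, 100))
  cfg <- silence_config()
  # I_ref = 0 + 0.95 * 100 = 95; T = 0 + 0.65 * 95 = 61.75
  expect_equal(silence_threshold(ic, cfg), 61.75)

  # boundary: both fractions 1 -> threshold at the maximum
  expect_equal(silence_threshold(ic, silence_config(1, 1)), 100)

  # dB-offset invariance
  ic20 <- make_contour(ic$values + 20)
  expect_equal(silence_threshold(ic20, cfg),
               silence_threshold(ic, cfg) + 20)

  expect_error(silence_threshold(make_contour(rep(3, 10)), cfg),
               "flat", class = "ppa_degenerate_error")
})

test_that("planted silences are recovered within one analysis window", {
  sim <- synth_audio(speech_sandwich(0.2), rate = test_rate, seed = 7)
  res <- analyze_silences(sim$waveform)
  expect_equal(nrow(res$silences), 1)
  expect_lt(abs(res$silences$start - 0.4), 0.032)
  expect_lt(abs(res$silences$end - 0.6), 0.032)
  expect_lt(abs((res$silences$end - res$silences$start) - 0.2), 0.032)
})

test_that("a 10 ms gap yields no silence (15 ms minimum)", {
  sim <- synth_audio(speech_sandwich(0.010), rate = test_rate, seed = 8)
  res <- analyze_silences(sim$waveform)
  expect_equal(nrow(res$silences), 0)
  expect_equal(res$metrics$pst, 0)
  expect_equal(res$metrics$arcsin_pst, 0)
  expect_true(is.na(res$metrics$median_s))
})

test_that("silences separated by <30 ms of speech merge", {
  segs <- data.frame(kind = c("speech", "silence", "speech", "silence",
                              "speech"),
                     duration_s = c(0.4, 0.1, 0.020, 0.1, 0.4),
                     level_db = -20)
  sim <- synth_audio(segs, rate = test_rate, seed = 9)
  res <- analyze_silences(sim$waveform)
  expect_equal(nrow(res$silences), 1)
  expect_equal(res$silences$end - res$silences$start, 0.22,
               tolerance = 0.2)   # ~0.22 s merged silence
  expect_lt(abs((res$silences$end - res$silences$start) - 0.22), 0.032)
})

test_that("rule order on a hand-built contour: absorb, discard, trim", {
  # frames at 8 ms; 0 = silent (below T), 60 = speech
  v <- c(rep(0, 10),            # leading silence  -> trimmed
         rep(60, 20),
         rep(0, 5),             # 40 ms silence    -> kept
         rep(60, 2),            # 16 ms speech     -> absorbed
         rep(0, 5),             # 40 ms silence    -> merged with above
         rep(60, 20),
         rep(0, 1),             # 1-frame silence (32 ms) -> discarded
         rep(60, 20),
         rep(0, 8))             # trailing silence -> trimmed
  ic <- make_contour(v)
  # a single sub-threshold frame implies ~one window of true silence, so
  # the duration floor only bites above window_s; raise it to see it fire
  sil <- detect_silences(ic, silence_config(min_silence_s = 0.040))
  expect_equal(nrow(sil), 1)
  span <- attr(sil, "span")
  # leading silence trimmed: span starts at its end, not at 0
  expect_gt(span[1], 0.05)
  expect_lt(span[2], max(ic$times))
  # merged run spans 12 frame centres (5 + 2 absorbed + 5) plus a
  # half-window extension on each side
  expect_equal(sil$end - sil$start, 11 * 0.008 + 0.032, tolerance = 1e-9)
})

test_that("exclusion intervals are cut from silences and denominator", {
  v <- c(rep(60, 20), rep(0, 25), rep(60, 20))   # one 200 ms silence
  ic <- make_contour(v)
  sil0 <- detect_silences(ic, silence_config())
  excl <- intervals(sil0$start[1], sil0$start[1] + 0.05)
  sil <- detect_silences(ic, silence_config(), exclusions = excl)
  expect_equal(attr(sil, "excluded_s"), 0.05)
  expect_equal(sum(sil$end - sil$start),
               sum(sil0$end - sil0$start) - 0.05)
  m <- silence_metrics(sil)
  m0 <- silence_metrics(sil0)
  span_len <- diff(attr(sil0, "span"))
  expect_equal(m$pst,
               (m0$pst * span_len - 0.05) / (span_len - 0.05))
})

test_that("silence metrics closed forms", {
  m <- silence_metrics(intervals(0.1, 0.3), span = c(0, 1))
  expect_equal(m$pst, 0.2)
  expect_equal(m$arcsin_pst, asin(sqrt(0.2)))
  expect_equal(round(m$arcsin_pst, 4), 0.4636)

  m3 <- silence_metrics(intervals(c(0, .2, .4), c(.1, .3, .5)),
                        span = c(0, 1))
  expect_equal(m3$median_s, 0.1)
  expect_equal(m3$mad_s, 0)

  m_spread <- silence_metrics(intervals(c(0, .2, .5), c(.05, .3, .7)),
                              span = c(0, 1))
  expect_equal(m_spread$median_s, 0.1)   # durations 50/100/200 ms
  expect_equal(m_spread$mad_s, 0.05)

  expect_error(silence_metrics(intervals(0, 2), span = c(0, 1)),
               "outside", class = "ppa_validation_error")
})

test_that("MAD/median shift behaviour and detection scale invariance", {
  durs <- c(0.05, 0.1, 0.2)
  base <- silence_metrics(intervals(cumsum(durs) - durs + 0.01,
                                    cumsum(durs) + 0.01), span = c(0, 1))
  shifted_durs <- durs + 0.03
  sh <- silence_metrics(intervals(c(0, 1, 2), c(0, 1, 2) + shifted_durs),
                        span = c(0, 3))
  expect_equal(sh$mad_s, base$mad_s)                 # MAD shift-invariant
  expect_equal(sh$median_s, base$median_s + 0.03)    # median equivariant

  sim <- synth_audio(speech_sandwich(c(0.15, 0.25)), rate = test_rate,
                     seed = 21)
  r1 <- analyze_silences(sim$waveform)
  scaled <- waveform(sim$waveform$samples * 0.05, test_rate)
  r2 <- analyze_silences(scaled)
  expect_equal(r1$silences$start, r2$silences$start)
  expect_equal(r1$silences$end, r2$silences$end)
  expect_equal(r1$metrics$pst, r2$metrics$pst)
})

test_that("k planted silences are recovered across seeds (property)", {
  for (seed in 1:5) {
    k <- 2 + seed %% 3
    durs <- seq(0.06, by = 0.04, length.out = k)
    sim <- synth_audio(speech_sandwich(durs, speech_s = 0.15),
                       rate = test_rate, seed = seed)
    res <- analyze_silences(sim$waveform)
    expect_equal(nrow(res$silences), k)
    expect_true(all(abs(res$silences$start - sim$truth$start) < 0.032))
    expect_true(all(abs(res$silences$end - sim$truth$end) < 0.032))
  }
})
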