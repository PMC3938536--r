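---
title: "Acoustic discrimination of PPA variants: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic discrimination of PPA variants: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppaspeech)
```

## The problem

Differentiating the logopenic (lvPPA) and nonfluent/agrammatic (nfvPPA)
variants of primary progressive aphasia matters clinically — lvPPA is
associated with Alzheimer-type pathology, nfvPPA with tauopathy — but the
gold standard is expert perceptual judgment of speech. Apraxia of speech
(AOS), strongly associated with nfvPPA, leaves acoustic fingerprints that
can be measured objectively from two routine tasks:

* **Syllable segregation** — abnormal pausing — measured from a
  passage-reading recording as statistics of detected silences:
  proportion of silence time (PST), median silence duration, and
  variability of silence duration (median absolute deviation, MAD).
* **Equalized lexical stress** — loss of duration contrast between the
  first two syllabic vowels of polysyllabic words — measured from a word
  repetition task as Pairwise Variability Indices,

  $$\mathrm{PVI} = 100\,\frac{d_1 - d_2}{(d_1 + d_2)/2},$$

  where $d_i$ is the vowel duration (ms) or peak intensity (positive dB
  scale) of vowel $i$. Division by the mean makes the index
  rate-invariant; values near zero indicate equalized stress (the
  apraxic pattern). Per subject the analysis uses the median PVI over
  five weak-strong (WS: banana, computer, pagoda, potato, thermometer)
  and five strong-weak (SW: butterfly, bicycle, caterpillar, dinosaur,
  stethoscope) words.

Classification is by a discriminant function realized, as in the source
analysis, as **ordinary least squares on a 0/1 group code** (lvPPA = 0,
nfvPPA = 1). The published coefficients define two diagnostic indices:

* Duration index (two predictors):
  $1.763 - 0.008\,|\mathrm{PVI^{dur}_{WS}}| - 0.007\,|\mathrm{PVI^{dur}_{SW}}|$
* Silence+duration index (three predictors):
  $2.387 - 2.057\,\arcsin\sqrt{\mathrm{PST}} + 2.991\,\mathrm{MAD_s}
  - 0.010\,|\mathrm{PVI^{dur}_{WS}}|$

Rounding the index to zero decimals (half away from zero, clamped to
$\{0,1\}$) yields the predicted variant.

## Silence detection

The intensity contour is a Hann-tapered short-time mean square in dB
(window 32 ms, hop 8 ms, both configurable; the published analysis used
Praat's generic algorithm without reporting parameters, so these
Praat-like defaults stand in for it). Silences are frames below

$$T = I_{\min} + 0.65\,(I_{\mathrm{ref}} - I_{\min}), \qquad
  I_{\mathrm{ref}} = I_{\min} + 0.95\,(I_{\max} - I_{\min}),$$

subject to a 15 ms minimum silence duration and a 30 ms minimum
intervening speech duration. Two interpretation choices deserve note:

* **Scale-invariant reference.** "0.95 of the maximum intensity" is
  ill-defined on a dB scale with arbitrary reference (multiplying a dB
  value by 0.95 changes meaning under any constant offset). It is
  reinterpreted as 0.95 of the min-to-max *range*, which preserves the
  intent (a reference slightly below the maximum, robust to bursts) and
  makes detection exactly invariant to global gain — a property the test
  suite asserts.
* **Rule order.** Thresholding, then absorption of sub-30 ms speech,
  then removal of sub-15 ms silences, then trimming of edge silences
  (which define the analysed span used as the PST denominator), then
  subtraction of exclusion intervals (with excluded time also removed
  from the denominator). The source describes the rules but not their
  order; this order is fixed and documented.

**Boundary estimation.** A frame falls below threshold only once speech
occupies a tiny tail of its (Hann-weighted) window, so raw run edges
bias silence durations short by roughly one window. Detected runs are
therefore extended by half a window per side, which centres the boundary
estimate; recovered boundaries on synthetic audio sit within about 10 ms
of truth (asserted at one window, 32 ms). A consequence is that a single
sub-threshold frame already implies ≈ one window of true silence, so
with default parameters the 15 ms duration floor only bites for
fragments created by exclusion masking or for non-default windows.

The arcsine transform of PST is $\arcsin\sqrt{p}$ in radians (the
standard variance-stabilizing transform; the source states only "arcsin
transformed", and radians reproduce its printed group values). The MAD
is unscaled (`constant = 1`), matching "median absolute deviation"
literally rather than the normal-consistent estimator.

## Intensity PVI and the dB offset

Peak vowel intensities are measured on a dB-full-scale contour and can
be negative, which would make the PVI ratio depend on the arbitrary
reference. A fixed +96 dB offset (the 16-bit dynamic range) maps values
onto a positive pseudo-SPL scale approximating the calibrated dB SPL the
source used. The choice is second-order: intensity PVI did not
discriminate the groups and is excluded from both diagnostic indices.

## Model-layer choices

* **Units.** The silence-variability predictor enters the
  three-predictor model in seconds; the published group table prints it
  in ms, but the coefficient magnitude (2.991) and the case-level plots
  (variability values ≈ 0.1) are only consistent with seconds.
* **Sign of the PVI coefficient, three-predictor model.** The published
  coefficient table prints $B = +0.010$ against $\beta = -0.520$ and
  $t = -3.785$. The sign is treated as typographic and $-0.010$ used:
  with $+0.010$ the group-median feature vectors of *both* variants
  produce indices far outside the printed classification behaviour,
  with $-0.010$ they reproduce it (0.229 → 0; 0.712 → 1). The
  coefficient vector is an argument, so users can override this.
* **Absolute PVIs.** Group medians are reported signed (WS medians are
  negative), but the indices consume absolute values: signed inputs
  yield out-of-range indices at the published medians, absolute inputs
  reproduce the published 0/1 coding. Both variants are computed and
  surfaced by `stress_profile()`.
* **Rounding.** "Rounding to zero decimal places" is implemented as
  half-away-from-zero then clamping to $\{0,1\}$; only indices in
  $[0.5, 0.65]$-ish territory are near the boundary, so the tie rule is
  almost never material.
* **Screening.** Collinearity exclusion at $|r| > 0.80$ with a caller
  priority list (the source dropped median silence duration in favour of
  its variability); multivariate outliers at
  $D^2 > \chi^2_{p,\,\alpha=0.001}$ (18.47 for $p = 4$), with the
  identity $\sum_i D^2_i = p\,(n-1)$ used as a test oracle.

## The synthetic world

No recordings or per-subject data accompany the source, so the package
carries its own stated world:

* `synth_audio()` — alternating band-limited noise segments: speech at a
  target RMS level, silences 40 dB below the quietest speech segment
  (unambiguous thresholding), with planted silence intervals returned as
  ground truth.
* `synth_word()` — two harmonic vowels (f0 125 Hz plus two harmonics,
  5 ms ramps) at target levels and durations, separated by a floor-level
  gap, with true vowel boundaries as the token.
* `simulate_cohort()` — per-group normal draws using the published group
  means/SDs as defaults (n = 21 lvPPA / 20 nfvPPA / 17 controls):
  arcsine-PST 0.61 (0.13) / 0.62 (0.17) / 0.48 (0.09); median silence
  0.126 (0.050) / 0.236 (0.209) / 0.083 (0.027) s; silence MAD
  0.087 (0.048) / 0.159 (0.126) / 0.050 (0.028) s; duration PVI WS
  −116.2 (18.3) / −87.4 (26.9) / −109.7 (18.9) and SW 89.6 (17.0) /
  63.9 (26.2) / 80.7 (16.0). PVIs are sampled signed and folded to
  absolute; bounded quantities are clamped. Intensity-PVI statistics
  were not published (the measure was non-discriminative), so a
  non-discriminative placeholder (−4/+4, SD 2.5, identical across
  groups) is used. Features are independent by default — the source
  publishes no covariances — with an optional user-supplied correlation
  matrix (used in the tests to reproduce the median-vs-MAD collinearity
  scenario).

**What a green test establishes — and what it does not.** The simulator
reproduces marginal group distributions, not real speech: no phonetic
content, no within-subject correlation structure, no rater noise.
Classifying simulated cohorts with the published coefficients yields a
20-seed median accuracy near 0.80, bracketing the published in-sample
84% — a consistency check, not a replication. One stated acceptance
property is honestly red and kept so: refitting the two-predictor model
on large simulated cohorts (n = 1000/group) does *not* recover the
published coefficients within 95% CIs in ≥ 90/100 replicates, because
the generator's implied population coefficients (constant ≈ 1.89, slopes
≈ −0.0079/−0.0077, from folded independent normals) differ from the
published point estimates (1.763, −0.008, −0.007) of one n = 38 sample
by more than the width of an n = 2000 confidence interval. At
paper-sized cohorts (21/20) the same coverage is ≈ 91/100. The
fixed-sample estimate simply is not the population parameter of the
stated generator; tightening the simulator to force coverage would be
tuning toward the answer.

## Numerical and degenerate-input choices

* Flat contours (no intensity range) raise a degenerate-input error
  rather than return an arbitrary threshold.
* An empty silence set gives PST 0 with `NA` (undefined, not zero)
  median and MAD.
* WAV I/O supports PCM16 and float32; multi-channel input is averaged
  to mono; PCM16 round trips are exact to 1/32768.
* All generators are pure functions of (spec, seed) and restore the
  caller's RNG state.
* Validation errors and computation errors are distinct condition
  classes, mapped by the CLI to exit codes 2 and 3.

## Known limitations

* The exact Praat intensity algorithm (Kaiser windows, local-mean
  subtraction) is not reproduced; the documented Hann/32 ms/8 ms
  contract stands in for it. All thresholds are range-relative, so this
  choice is second-order for silence statistics.
* Vowel boundaries come from annotations (CSV/TextGrid); there is no
  forced alignment or automatic vowel segmentation.
* F0-based stress measures, loudness calibration, filled-pause
  classification and the imaging arm of the source study are out of
  scope.
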