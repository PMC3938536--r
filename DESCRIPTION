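Package: ppaspeech
Title: Acoustic Speech Biomarkers for Primary Progressive Aphasia Variants
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts acoustic markers of apraxia of speech from mono
    speech recordings and classifies logopenic versus nonfluent variants
    of primary progressive aphasia (PPA). Implements silence detection
    from windowed intensity contours (proportion of silence time, median
    silence duration, and median-absolute-deviation variability),
    Pairwise Variability Indices (PVI) of vowel duration and peak
    intensity for polysyllabic word tokens, predictor screening
    (skewness/kurtosis, multicollinearity, Mahalanobis outliers),
    discriminant-function classification realized as least-squares
    regression of a binary group code, and published-coefficient
    diagnostic indices. A synthetic-data module generates pseudo-speech
    audio with known silence and vowel ground truth and simulates
    subject cohorts with the published group statistics, so the whole
    pipeline is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
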