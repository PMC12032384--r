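Package: pavcal
Title: Calibration of Psychophysiological Measures of Pavlovian Reward
    Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies Pavlovian reward conditioning and 7-day memory
    retention from four psychophysiological channels: heart period
    responses (HPR), skin conductance responses (SCR), pupil size
    responses (PSR) and respiration amplitude responses (RAR). Implements
    linear time-invariant response-function models for each channel,
    channel-specific preprocessing (inter-beat-interval filtering and
    interpolation, skin-conductance range and slope artifact rules, pupil
    validity/gaze/foreshortening correction, respiration cycle
    detection), convolution general linear model inversion (trial-wise
    and condition-wise), peak-scoring baselines for pupil dilation, and a
    retrodictive-validity layer (paired t tests, small-sample-corrected
    Hedges g, trial-subset scans, halves analyses, Holm-Bonferroni
    correction). A forward simulator generates synthetic differential
    conditioning cohorts with known injected effects so the whole
    pipeline can be validated against ground truth without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
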