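Package: orsmoke
Title: Operating-Room Electrocautery Smoke Exposure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing occupational exposure to volatile organic
    compounds (VOCs) released by electrocautery devices in operating rooms,
    as measured by real-time proton-transfer-reaction mass spectrometry.
    Provides a curated harmful-VOC panel with OSHA/NIOSH exposure limits,
    blank subtraction and single-point calibration of 1 Hz concentration
    time series, per-operation summaries (mean, maximum, time-of-maximum),
    inhaled-dose and breath-uptake estimation, exposure-limit exceedance
    screening, cigarette-equivalence, and study-level statistics for
    randomized smoke-evacuation trials (two-group comparisons, binary-factor
    least-squares effect decomposition, sample-size computation, and a
    Kolmogorov-Smirnov test for early clustering of concentration maxima).
    A synthetic operating-room air simulator with known ground truth makes
    every stage testable without access to raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
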