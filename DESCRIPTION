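Package: accelcal
Title: Accelerometer Cut-Point Calibration for Walking-Speed Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates accelerometer count thresholds (cut points) that
    separate slow, intermediate and brisk walking from instructed walking
    bouts, and cross-validates them. Walking bouts are stratified by the
    75th percentile of self-selected slow speed and the 25th percentile of
    self-selected brisk speed; cut points are chosen from empirical ROC
    curves under deterministic sensitivity/specificity priority rules, and
    validated by leave-one-out cross-validation with absolute agreement and
    quadratic weighted Cohen's kappa (participant-level bootstrap CI). A
    synthetic cohort generator reproduces the count-versus-speed structure
    of hallway walking studies so the full pipeline is testable without raw
    device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
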