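Package: shakeval
Title: Shaker-Table Validation of Raw Wearable Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses mechanical shaker-table validation studies
    of raw triaxial accelerometry from research-grade and consumer wearable
    devices. Models an orbital shaker (frequency to centripetal-acceleration
    conversion), builds reliability and validity trial protocols, generates
    synthetic raw device streams with realistic hardware characteristics
    (sampling rate, dynamic-range clipping, bias, gain, noise, dropout),
    processes streams to second-level ENMO (Euclidean Norm Minus One, in
    milligravity), and computes the full agreement battery against the
    shaker-derived reference: two-way random-effects absolute-agreement
    intraclass correlation, Pearson correlation, Lin's concordance correlation
    coefficient, absolute error, mean bias with limits of agreement,
    Bland-Altman exports, and two-one-sided-tests (TOST) equivalence testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
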