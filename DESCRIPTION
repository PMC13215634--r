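Package: bracewear
Title: Sensor-Based Measurement of Knee-Brace Wear Time and Agreement with
    Self-Report
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for objectively measuring orthosis wear time from an
    embedded temperature sensor and quantifying how well self-reported wear
    agrees with it. Includes a physics-based synthetic cohort generator
    (Newtonian skin/ambient relaxation, sensor noise and quantization,
    biased and incomplete daily self-report logs), a gradient-based
    donning/doffing detector, calendar-day aggregation with 3- and 7-day
    rolling averages, agreement analysis via Lin's concordance correlation
    coefficient and Bland-Altman 95% limits of agreement with
    repeated-measures-aware confidence intervals (cluster bootstrap), and
    the standard missing-log sensitivity analyses (impute-as-no-wear,
    exclude high-missingness participant).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
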