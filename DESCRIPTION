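Package: serialvh
Title: Serial Intravascular Ultrasound Virtual-Histology Plaque Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-based morphometry and tissue-composition analysis for
    serial (baseline / follow-up) intravascular ultrasound virtual-histology
    (IVUS-VH) pullbacks. Provides six-category plaque phenotype
    classification with thin-cap fibroatheroma (TCFA) run confirmation,
    the Liverpool Active Plaque Score (LAPS) at frame, 5-mm segment and
    pullback level, landmark-based co-registration of sequential pullbacks
    into paired 5-mm vessel segments, phenotype-transition and TCFA-fate
    analysis, group statistics with patient-level random effects, and a
    calibrated synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
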