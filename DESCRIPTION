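Package: bimotap
Title: Bimanual Finger-Tapping Coordination Analysis and Age-Cutoff Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bimanual thumb-index finger-tapping
    recordings as a screening instrument for age-related decline in
    bimanual coordination. Provides a synthetic-trial generator that
    emulates magnetic-sensor distance waveforms for in-phase and
    anti-phase tapping tasks across young, young-old and old-old adult
    groups; extraction of the nine standard coordination parameters
    (travel distance, local-maximum amplitude statistics, fatigue slope,
    tap counts and interval statistics, inter-hand phase-difference
    variability); mixed-design analysis of variance with Bonferroni
    post-hoc contrasts; age correlations; and ROC/Youden-index age
    cutoffs with Hanley-McNeil standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    car,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
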