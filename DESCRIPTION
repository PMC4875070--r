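Package: peakrpe
Title: Predicting Children's Peak Oxygen Uptake from Submaximal Perceived
    Exertion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating peak oxygen uptake (VO2peak) in children
    from submaximal ratings of perceived exertion (RPE) collected during a
    single graded treadmill exercise test. Implements per-participant
    linear regressions on the Children's Effort Rating Table (CERT) and
    log-log power regressions on the curvilinear Eston-Parfitt (EP) scale,
    extrapolation of the fitted perceptual response to terminal (RPE 9)
    and theoretical maximal (RPE 10) endpoints, and a criterion-validity
    agreement battery: Pearson correlations with agreement categories,
    the standard error of estimate in absolute, standardized and relative
    form, paired t tests, and one-way ANOVA with Bonferroni-adjusted post
    hoc contrasts. A calibrated synthetic graded-exercise-test cohort
    generator makes every pipeline stage testable without participant
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
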