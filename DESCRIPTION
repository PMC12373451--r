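Package: wayfindr
Title: Education Effects on Spatial Wayfinding from Game Trajectory Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how education relates to spatial wayfinding ability
    measured from navigation-game trajectory lengths. Provides a synthetic
    cohort generator with the demographic and performance structure typical of
    large mobile-game navigation studies (age-related decline, a male advantage,
    a tertiary-education advantage growing with age and task difficulty,
    country-level heterogeneity, and an optional school-leaving-age reform
    discontinuity in a birth cohort); inclusion filtering with an audit trail;
    a principal-component wayfinding-performance composite normalized by
    tutorial-level performance; effect-size analyses (bias-corrected
    standardized mean differences with confidence intervals, age-window
    profiles, factorial ANOVA, default Bayes factors) and random-slope mixed
    models of the education effect by country and by level; and a sharp
    regression-discontinuity analysis of a school-leaving-age reform with a
    cutoff sweep, gap extrapolation, IQ-point rescaling, and a placebo outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
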