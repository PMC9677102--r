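Package: wstrans
Title: Continuous-Time Multistate Markov Analysis of Childhood Weight-Status Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transitions between normal weight, overweight,
    and obesity in longitudinal child cohorts observed at annual examinations.
    Provides BMI computation and age/sex-specific cutoff classification,
    adiposity-rebound (BMI nadir) estimation from mixed-effects quadratic
    growth curves, a from-scratch time-homogeneous three-state Markov engine
    for interval-censored panel data (matrix-exponential likelihood, maximum
    likelihood estimation, proportional-intensity covariate effects, hazard
    ratios, likelihood-ratio model comparison), derived summaries (transition
    probabilities at arbitrary horizons, mean sojourn times, total length of
    stay, prevalence projection and a projection validation rule), and a
    synthetic-cohort generator for end-to-end testing and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    MASS,
    lme4,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
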