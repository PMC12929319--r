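Package: hsuvlong
Title: Longitudinal Models for EQ-5D-3L Health-State Utility Values After
    Kidney Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the longitudinal evolution of EQ-5D-3L health-state
    utility values (HSUVs) in kidney-transplant recipients from routinely
    collected clinical data. Implements four mixed-effects model families for
    bounded utilities -- a linear mixed model, a mixed beta regression, a
    mixed two-part (zero-inflated) beta regression and a mixed adjusted
    limited dependent variable mixture model (ALDVMM) -- estimated by
    marginal maximum likelihood with adaptive Gauss-Hermite quadrature.
    Includes value-set scoring of EQ-5D-3L profiles, the decrement rescaling
    and boundary-compression transforms used by beta-family models, a
    piecewise-linear time basis split at one year post-transplantation,
    likelihood-ratio covariate selection, precision and decile-calibration
    evaluation, utility-trajectory and QALY prediction, and a synthetic
    cohort generator emulating a large French transplant cohort so every
    stage is testable without patient-level data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmmTMB,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
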