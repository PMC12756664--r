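Package: rdscreen
Title: Sharp Regression-Discontinuity Analysis of Threshold-Triggered Health Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for sharp regression-discontinuity (RD)
    evaluation of threshold-triggered screening programmes, motivated by
    BMI-based referral at a 25 kg/m2 cutoff. Provides kernel-weighted local
    polynomial estimation with additive covariate adjustment, a documented
    plug-in MSE-optimal bandwidth selector with multiplicative sensitivity
    scaling, manipulation (density) and covariate/attrition continuity
    diagnostics, placebo-cutoff and donut robustness checks, modified Poisson
    risk-ratio RD for binary outcomes, subgroup interaction analysis, and
    simulation-based power, all driven by a seeded synthetic-cohort generator
    with the statistical structure the design assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    sandwich,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
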