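Package: pa1c
Title: Personalized HbA1c from Continuous Glucose Monitoring via the
    Apparent Glycation Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the kinetic-model personalization of hemoglobin A1c
    using continuous glucose monitoring (CGM) data collected under a
    three-sensor-wear protocol. Computes consensus glycemic metrics (mean
    glucose, coefficient of variation, time in glucose ranges), performs
    quality control of the wear protocol, estimates each subject's apparent
    glycation ratio (AGR) from a calibration period, maps later A1c
    measurements onto the reference-glycator scale (personalized A1c, pA1c),
    and runs the cohort-level statistical comparison of how well measured A1c
    and pA1c track mean glucose (regression, correlation, Welch tests,
    stepwise-AIC covariate adjustment, and correlation power analysis). A
    synthetic-cohort simulator with known ground-truth glycation parameters
    makes the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
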