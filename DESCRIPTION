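Package: score2val
Title: External Validation Toolkit for the SCORE2 Cardiovascular Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to externally validate the four region-specific SCORE2
    10-year cardiovascular risk prediction models in routine health-care
    cohorts with competing risks, socioeconomic and ethnic subgroups, and
    substantial missingness. Provides the SCORE2 Fine-Gray risk engine with
    region recalibration (coefficients supplied as configuration data), a
    person-level cohort data model with eligibility and follow-up rules,
    multiple imputation by chained equations with Rubin's-rules pooling,
    fixed-horizon calibration (observed/expected ratios, decile calibration
    curves) and discrimination (Harrell's C) under competing risks, subgroup
    stratification with treatment-eligibility shifts, and a synthetic cohort
    generator that emulates the covariate structure, censoring and
    missing-at-random mechanisms of a Dutch primary-care population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    cmprsk
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
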