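Package: mrdose
Title: Linear and Nonlinear Mendelian Randomization for Lipid Dose-Response
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Instrumental-variable analysis of quantitative exposures against
    binary disease and cause-specific mortality outcomes using genetic risk
    scores. Implements weighted genetic risk score construction with
    instrument diagnostics, ratio-method Mendelian randomization with
    inverse-variance weighted, MR-Egger, weighted median and
    contamination-mixture sensitivity estimators, multivariable Mendelian
    randomization with conditional instrument-strength statistics, and
    nonlinear Mendelian randomization by doubly ranked stratification with
    fractional polynomial dose-response meta-regression. Association models
    cover linear and logistic regression and Cox regression on the attained
    age timescale with delayed entry and cause-specific censoring. A
    synthetic cohort generator with known causal curves supports method
    validation without access to individual-level biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
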