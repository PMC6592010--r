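Package: expvat
Title: Objective Ventilatory Anaerobic Threshold Estimation from
    Cardiopulmonary Exercise Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the ventilatory anaerobic threshold (VAT) from
    breath-by-breath ramp cardiopulmonary exercise testing (CPX) data by
    exponential curve fitting of the V-slope (VCO2 versus VO2) and of the
    VO2-VE relation. Provides the closed-form tangent estimators
    expVAT(VCO2) and expVAT(VE), the oxygen uptake efficiency slope
    (OUES) for VE and VCO2, quality-control rules (iterative Grubbs
    screening of fit quality, pre-threshold slope validity), agreement
    statistics (Bland-Altman limits of agreement, Williams's test for
    dependent correlations), truncation sensitivity analyses, and a
    seeded breath-by-breath ramp-test simulator with known true
    thresholds for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
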