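Package: pannenct
Title: Multiphase CT Enhancement Ratios, 3D First-Order Texture and Grade
    Statistics for Pancreatic Neuroendocrine Neoplasms
Version: 0.1.0
Authors@R:
    person("panNEN", "CT Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify multiphase contrast-enhanced CT of pancreatic
    neuroendocrine neoplasms (panNENs) for tumor-grade prediction: circular-ROI
    attenuation measurement with ROI propagation across contrast phases, the seven
    enhancement and permeability ratios, first-order (histogram) texture features
    of a 3D tumor segmentation (mean, variance, skewness, excess kurtosis,
    entropy), nonparametric grade-group statistics (chi-squared, Mann-Whitney U,
    pooled t) with ROC cutoff analysis, and a synthetic multiphase CT phantom
    cohort generator with analytic ground truth so the whole pipeline can be
    exercised and validated without patient data. Includes minimal NIfTI-1
    volume input/output and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
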