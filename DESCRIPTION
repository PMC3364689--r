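Package: qpprpbpk
Title: Screening-Level QPPR Prediction of VOC Intrinsic Clearance with
    PBPK Confidence-Bound Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates a quantitative property-property relationship (QPPR)
    that predicts the phospholipid-referenced intrinsic metabolic clearance of
    volatile organic chemicals (VOCs) from log octanol:water and blood:water
    partition coefficients and the calculated ionization potential, with
    leave-one-out Q2 validation, variance-inflation diagnostics and 95%
    mean-confidence intervals. The confidence bounds are propagated through a
    four-compartment gas-exchange-lung human inhalation PBPK model (well-
    stirred liver, hepatic extraction ratio) to bound venous-blood kinetics
    and the 24 h area under the curve, and the reliability of the resulting
    dose-metric predictions is classified on a sensitivity-by-uncertainty
    grid. Ships the 26-chemical calibration and 11-chemical evaluation panels
    as validated fixtures and a seeded synthetic-chemical generator for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
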