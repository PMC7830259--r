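Package: cmskinetics
Title: Kinetics of Colistimethate Acidic Hydrolysis and LC-MS Quantitation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the acid-catalysed hydrolysis of colistimethate (CMS), the
    prodrug of colistin (CS), as a reversible first-order reaction CMS <-> CS.
    Provides exact and numerically integrated concentration trajectories,
    estimation of forward and reverse rate constants from percent-remaining
    time series (early-window log-linear regression and full-course nonlinear
    least squares), Arrhenius modelling with temperature extrapolation,
    half-life and hydrolysis-completeness prediction, and the supporting
    bioanalytical quantitation statistics: calibration-curve fitting and
    pooling by the extra sum-of-squares F test, limits of detection and
    quantitation, colistin A/B partitioning, indirect CMS determination, and
    accuracy/precision summaries. Includes a seeded synthetic-data generator
    emulating the accelerated-stability study design, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
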