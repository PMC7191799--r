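Package: stargc
Title: Stochastic Targeted Glycaemic Control in Silico
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico toolkit for the STAR (Stochastic TARgeted) model-based
    glycaemic control framework for critically ill patients. Implements the
    ICING glucose-insulin-nutrition physiological model, hourly model-based
    identification of patient-specific insulin sensitivity (SI), kernel-density
    conditional transition models of future SI over 1-6 hour horizons, the
    risk-based insulin and nutrition dosing controller (Standard and
    Upper-Limit-Controlled variants), a closed-loop virtual-patient trial
    engine with fivefold by-patient cross-validation, synthetic cohort
    generation, and the standard glycaemic-control outcome metrics
    (time-in-band, workload, hypoglycaemia incidence). Supports quantifying
    the workload versus safety/efficacy trade-off of extended treatment
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
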