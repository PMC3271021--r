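Package: dynafba
Title: Dynamic Flux Balance Analysis for Batch Cultures with
    Multi-Substrate Monod Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates a multi-substrate Monod batch-kinetics model into
    genome-scale flux balance analysis (FBA) using the static optimization
    approach to dynamic FBA. Fits lag-phase Monod models to batch growth and
    metabolite curves by normalized least squares with bootstrap uncertainty,
    derives time-dependent exchange-flux constraints, and solves a sequence
    of pseudo-steady-state flux problems under a dual objective that trades
    off growth maximization against total squared flux, with the objective
    weight inferred by bi-level grid search. Also simulates time-integrated
    13C isotopomer labeling of proteinogenic amino acids from the dynamic
    flux series via isotopomer mapping matrices, and fits exchange
    coefficients describing pathway reversibility to GC-MS mass
    distribution data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    xml2,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
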