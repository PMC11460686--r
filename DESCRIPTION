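Package: cmcal
Title: Digital-Twin Calibration of iPSC-Derived Cardiomyocyte Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates action potentials and calcium transients of induced
    pluripotent stem cell-derived cardiomyocytes (iPSC-CMs) with a
    conductance-scalable ordinary differential equation model in the Kernik
    (2019) formulation, composes multi-condition experimental protocols with
    state carry-over, and calibrates the 16 maximal-conductance multipliers
    to raw or min-max normalized voltage/calcium traces with a genetic
    algorithm. Includes an in-silico dataset generator with ground-truth
    conductances, action-potential and calcium-transient feature extraction,
    arrhythmia-dynamics classification, I_Kr-block tolerance thresholds,
    regression-based parameter sensitivity analysis, and preprocessing of
    optical fluorescence recordings (baseline-drift erosion, median
    filtering, resampling, normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
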