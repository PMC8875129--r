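Package: caco2trans
Title: Bidirectional Transport Analysis for Caco-2 Monolayer Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for bidirectional Caco-2 cell monolayer
    transport assays: segmented calibration-curve fitting with
    back-calculation and precision/recovery QC, transepithelial electrical
    resistance (TEER), sampling-dilution-corrected cumulative transport,
    apparent permeability coefficients (Papp), efflux ratios with
    mechanism classification, and inhibitor or co-administration effect
    analysis. Includes a mechanistic two-compartment Transwell simulator
    with passive permeation, saturable carrier-mediated efflux and
    sample-and-replace measurement, so every stage of the pipeline can be
    validated end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
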