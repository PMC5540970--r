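Package: monotol
Title: System Dynamics Modelling of the Human Monocyte Response to Endotoxin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the activation of resting human monocytes by bacterial
    lipopolysaccharide (LPS), their transition into endotoxin tolerance (ET),
    and the resulting TNF-alpha and CCL2 kinetics, using a six-stock
    compartmental model with Hill dose-response modulation and a discrete
    delay in TNF production. Provides the full calibration workflow used to
    parameterise such models from monocyte culture data: one-phase decay
    estimation of activation rates from two-stimulus readouts, Hill
    dose-response regression, joint kinetic refinement against cytokine time
    courses, CCL2 parameter optimisation, and estimation of a tolerance index
    quantifying ET intensity. Includes scenario presets, a synthetic-data
    generator for the two-stimulus protocol, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
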