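Package: celia
Title: Simulation and Endpoint Quantification for Coupled
    Exponential-to-Linear DNA Amplification Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic reaction-network models of coupled
    exponential-to-linear isothermal DNA amplification circuits built from
    the polymerase-exonuclease-nickase (PEN) toolbox: an EXPAR-like
    autocatalytic switch, a tunable linear amplifier, a molecular inverter
    (NOT gate) and a microRNA-to-trigger converter. Provides deterministic
    ODE simulation and a Gillespie stochastic oracle, extraction of
    amplification times, linear-phase gain, saturation and window from
    fluorescence traces, sigmoid calibration of endpoint signals with
    limit-of-detection estimation and inverse concentration estimation,
    fold-difference panel accuracy evaluation, and a synthetic plate-reader
    data generator with an optical noise model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
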