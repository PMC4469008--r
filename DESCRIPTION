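Package: dcimmune
Title: Delay-Differential Model of Dendritic-Cell Immunotherapy for Murine Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and calibration pipeline for a five-population delay
    differential equation model of dendritic-cell (DC) immunotherapy against
    B16/F10 melanoma in mice: Gompertz tumor growth, a closed-form pulsed DC
    forcing, activated and naive cytotoxic T lymphocyte pools with an
    activation delay, and Michaelis-Menten TGF-beta suppression of CTL
    killing. Provides a fixed-step fourth-order Runge-Kutta integrator with
    dense delay history, infusion-protocol simulation and sweeps (dose size,
    dosing interval, lymph-node arrival fraction, TGF-beta knockout), tumor
    diameter to cell-count conversion, Gompertz least-squares fitting,
    exhaustive-search therapy-parameter calibration scored by normalized RMSE,
    local parametric sensitivity analysis, and a synthetic mouse tumor-growth
    data generator matching the study's measurement design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
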