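Package: lnchemosim
Title: Steady-State Chemokine Transport and Gradient Formation in an Idealized Lymph Node
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-volume simulation of coupled lymph flow and CCL19/CCL21
    chemokine transport in an idealized three-dimensional mouse popliteal
    lymph node. Solves Darcy flow with Starling transvascular exchange,
    steady advection-diffusion-reaction equations for diffusible CCL19 and
    unbound CCL21 coupled to local kinetics of extracellular-matrix binding,
    CCR7 binding/desensitization/internalization/recycling, and
    ACKR4-mediated scavenging at the subcapsular sinus ceiling. Provides
    probe-line gradient analysis, across-cell concentration differences,
    knockout and low-flow scenario presets, and Latin-hypercube / partial
    rank correlation sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
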