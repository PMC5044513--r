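Package: hepaflow
Title: Flow, Solute Transport, and Oxygen Models for Perfusion Hepatocyte Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale finite-volume models of laminar perfusion in three
    flow-based hepatocyte culture devices: a membrane-oxygenated scaffold
    chamber, a fluidized alginate-bead bed, and a single-chamber device with
    an offset outlet. Solves steady incompressible (Brinkman) flow on
    boundary-fitted structured grids, extracts wall and scaffold-level shear
    stress, simulates transient advection-diffusion of a step-dosed test
    compound (once-through or recirculating) and steady oxygen transport with
    Michaelis-Menten cellular consumption and a smooth low-oxygen cutoff, and
    solves the radial diffusion-consumption problem inside alginate beads.
    Includes synthetic washout-experiment generators and manufactured
    solutions so every stage can be verified without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
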