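Package: gatescape
Title: Gating Order Parameters, Permeation Pathways and Proton
    Electrostatics for Membrane Transporter Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyses for characterising the functional state of major
    facilitator superfamily (MFS) transporter conformations: two-gate
    geometric order parameters with state classification, simplified
    pore-radius profiling and water-density gridding of permeation
    pathways, a finite-difference linearized Poisson-Boltzmann solver
    with focusing for position-resolved Born free-energy landscapes of
    a solvated proton in an implicit membrane, rotamer-library
    prediction of DEER spin-spin distance distributions, Daura
    conformational clustering, and a synthetic two-domain helical
    bundle generator so every stage is testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Matrix,
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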