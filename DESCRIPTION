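Package: palmcycle
Title: Kinetic Modelling of Multi-Site ZDHHC6 Palmitoylation Dynamics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic and stochastic modelling of the reversible
    multi-site S-palmitoylation of the acyltransferase ZDHHC6 by its
    upstream writer enzyme ZDHHC16 and the eraser thioesterase APT2.
    Implements the open synthesis/folding/degradation reaction network
    over the 2^m occupancy states of the m palmitoylatable cysteines
    (328, 329, 343), with total quasi-steady-state (tQSSA) enzyme
    kinetics including substrate competition; in-silico radiolabelling
    protocols (35S pulse-chase, 3H-palmitate incorporation and release,
    PEGylation stoichiometry); multi-objective genetic-algorithm
    calibration returning Pareto ensembles; steady-state, flux,
    half-life and perturbation analysis; and exact stochastic
    simulation with single-molecule tracking of palmitoylation cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Matrix,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
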