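Package: pnpadapt
Title: Adaptive Finite-Element Solver for Poisson-Nernst-Planck Electrodiffusion
    in Neural Microdomains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solves the coupled Poisson-Nernst-Planck (PNP) equations of ionic
    electrodiffusion on two-dimensional domains with membranes, using quadratic
    (P2) Lagrange finite elements, BDF2 implicit time stepping with a coupled
    Newton-Raphson solve, and Hodgkin-Huxley channel kinetics on the nodal
    membrane.  A hierarchical a-posteriori error estimator drives anisotropic
    mesh adaptation through four local operations (edge refinement, node
    elimination, edge swapping, node displacement), concentrating degrees of
    freedom in the nanometre-scale Debye layers next to the membrane.  Includes
    a slab benchmark with a closed-form membrane potential, tailored (graded)
    and uniform meshing strategies for comparison, a two-dimensional
    node-of-Ranvier action-potential demonstration, and Gmsh/VTU mesh exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
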