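Package: tcatsim
Title: Closed Multiphase Tumor-Growth Models with Entropy-Production Auditing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulators for closed macroscale multiphase (porous-medium)
    models of avascular tumor growth derived with the thermodynamically
    constrained averaging theory (TCAT).  Implements a two-phase
    (interstitial fluid + tissue solid) compositional reaction-transport
    model on 1-D Cartesian or spherical finite-volume grids, and a
    three-phase (wetting fluid, tumor cell fluid, solid scaffold)
    well-mixed dynamical system with interfacial-area, curvature and
    capillary-pressure evolution.  Reactions follow linear chemical-affinity
    kinetics; interphase mass transfer is driven by augmented chemical
    potential differences.  A built-in entropy-production auditor evaluates
    every flux-force term group of the restricted simplified entropy
    inequalities and certifies closures and trajectories against the second
    law of thermodynamics.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
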