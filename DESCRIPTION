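Package: phrisim
Title: Lumped-Parameter Simulation and Design of Physical Human-Robot
    Interaction Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling the physical coupling between human soft
    tissue and a wearable robot.  Builds lumped-parameter networks of point
    masses, rigid ternary links, straps and series viscoelastic contact
    units, integrates them through time with the Udwadia-Kalaba equation
    for constrained multibody dynamics (explicit or implicit solver
    policies), and extracts steady-state interface forces, relative
    displacements and lift-off events.  Also provides the quasi-static
    interface-design layer: the analytic minimum-peak-pressure two-region
    load distribution for a rigid attachment plate, a discrete
    unilateral-spring plate equilibrium solver, design sweeps over bias
    force and stiffness-profile gradient, and estimation of skin/dorsum
    stiffness from force-displacement indentation data with series-spring
    correction for instrument compliance, including a seeded synthetic
    indentation data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    tools,
    utils,
    yaml
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
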