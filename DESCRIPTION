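Package: trunkdyn
Title: Rod-Network Dynamics and Stereotypical Force Laws for Muscular-Hydrostat Trunks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-mass rod-network model of an elephant trunk treated as a
    muscular hydrostat. Builds a 50-node truss of longitudinal, radial and
    connective rods with truncated-cone mass allocation, integrates its
    equations of motion under gravity and axial muscle-analogue forces,
    estimates internal rod forces from motion-capture-style trajectories by
    per-timestep nonlinear least squares, fits per-segment multilinear
    "stereotypical" laws linking segment curvature and length to internal
    forces, and closes the loop with an open-loop reaching controller.
    Includes trajectory error metrics, hexahedral volume-conservation
    reporting, and a seeded synthetic-trial generator emulating planar
    bending and bending-plus-elongation reaching movements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
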