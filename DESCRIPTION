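Package: rotorque
Title: Torque Analysis of ATP-Driven Rotary Motors from 3D Tracking Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the torque of ATP-driven rotary molecular
    motors, such as the archaellar motor of Halobacterium salinarum, from
    marker-rotation assays. Simulates rotational Langevin dynamics of beads
    and tethered cells driven at constant torque, renders and tracks
    wedge-prism dual-spot image stacks in which axial position is encoded in
    spot-pair separation, recovers the 3D rotation plane and signed rotation
    rate, computes closed-form low-Reynolds-number drag coefficients with
    near-wall corrections, fits the constant-torque model
    f = T_a / (2 pi (gamma + gamma_a)) with bootstrap uncertainties, and
    evaluates the ATP-hydrolysis energy budget of rotation under n-fold
    cooperativity of a hexameric ATPase.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'hydrodynamics.R'
    'simulate.R'
    'render.R'
    'tracking.R'
    'geometry.R'
    'benchmark.R'
    'torque.R'
    'energetics.R'
    'io.R'
    'pipeline.R'
    'show-methods.R'
    'rotorque-package.R'
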