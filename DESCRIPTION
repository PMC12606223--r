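Package: jointfv
Title: Joint-Level Force-Velocity Analysis for Muscle-Driven Movement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing joint-level force-velocity (joint-FV)
    properties of agonist-antagonist muscle pairs. Implements Hill-type
    force-velocity primitives with third-order activation dynamics,
    construction of instantaneous joint-fv curves and the morphing joint-FV
    space they span, quadrant classification and trajectory metrics for
    movements through that space, a planar three-joint muscle-driven
    reaching simulator with PD excitation control and hand-force
    perturbations, packaged reaching scenarios, and publication-style
    joint-FV frame/animation and time-series visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    patchwork,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
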