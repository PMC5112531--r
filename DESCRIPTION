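Package: gyrogen
Title: Morphoelastic Simulation of Cortical Folding and Surface Growth Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study where gyri form on a growing cerebral cortex.
    Provides a finite-element simulator of a growing soft bilayer plate
    (multiplicative growth kinematics, near-incompressible neo-Hookean
    elasticity, damped explicit quasi-static relaxation) with homogeneous
    growth, a fast-growing central patch, or a stiffening central patch; a
    classifier that labels the plate centre as gyrus, sulcus or bank after
    folding; a cortical-surface analysis pipeline (principal curvature by
    local quadric fitting, closest-vertex cortical thickness, vertex-wise
    longitudinal growth-rate regression with goodness-of-fit filtering,
    pooled two-sample t tests); and a synthetic-data generator emulating
    longitudinal fetal white/pial surface pairs with region-dependent
    thickness growth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
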