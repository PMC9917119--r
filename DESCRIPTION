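Package: mempull
Title: Coarse-Grained Force Spectroscopy Simulations of Helical Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained models of helical membrane proteins in an
    implicit bilayer and simulates single-molecule pulling experiments
    (vertical AFM-style extraction and lateral magnetic-tweezers-style
    unfolding) with overdamped Langevin dynamics.  Every energy term
    (backbone hydrogen bonding, pairwise side-chain contacts, multibody
    burial, and the depth-dependent membrane burial potential) carries an
    independent strength scale factor so that its contribution to rupture
    forces can be probed.  Includes a complete rupture-event analysis
    pipeline: force-extension curves, prominence-based rupture detection,
    replica alignment of energy responses, NH bond-vector rotation analysis,
    contact and hydrogen-bond fractions, helicity timelines, Bell-Evans
    velocity extrapolation and worm-like-chain fits, plus a
    configuration-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
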