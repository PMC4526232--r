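Package: dynallo
Title: Force-Distribution and Entropy Analysis of Dynamic Allostery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect dynamic (entropic) allostery in homodimeric
    proteins from coordinate trajectories and inter-atomic pairwise forces.
    Implements residue-pairwise force-difference networks (force distribution
    analysis), punctual stress and replica-subset convergence diagnostics,
    quasi-harmonic and force-covariance configurational entropy estimators,
    methyl-axis and dihedral order parameters, principal component analysis of
    collective motions with motion-matrix comparison, and distance-distribution
    state classification. Ships a synthetic elastic-network dimer generator
    with analytic mode spectra, exact pairwise forces and planted allosteric
    pathways, so every stage of the pipeline can be validated against closed
    forms without external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
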