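Package: cytospread
Title: Agent-Based Simulation of Cytoneme-Mediated Wnt8a Transport During
    Zebrafish Epiboly
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Off-lattice, cell-centre simulation of morphogen dispersal by
    signaling filopodia (cytonemes) in the early zebrafish gastrula. A
    proliferating epiblast spreads over a circular yolk under
    Delaunay-neighbour spring forces; marginal source cells extend
    stochastically growing and retracting cytonemes that deposit Wnt8a ligand
    onto receiving cells; receivers decay ligand exponentially and are
    thresholded into hindbrain versus forebrain/midbrain fates. Includes
    ensemble drivers, angular fate-profile binning, midbrain-hindbrain
    boundary estimation, log-normal cytoneme-length fitting, condition
    presets (ligand overexpression, Vangl2-lengthened cytonemes, combined,
    and cytoneme-number rescue), and a grid-search length calibration
    utility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
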