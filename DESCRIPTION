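Package: psdmeso
Title: Mesoscale Simulation of Multiphase Postsynaptic Density Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Particle-based reaction-diffusion simulator and analysis toolkit
    for liquid-liquid phase separation of postsynaptic density proteins.
    Proteins (AMPAR(TARP)4, NMDAR, PSD-95, CaMKII) are represented at domain
    resolution as spherical particles propagated by overdamped Langevin
    dynamics.  Specific domain-domain binding is a stochastic virtual
    reaction that rigorously enforces interaction valency and mutual
    exclusion of competing binding motifs; non-specific excluded volume is a
    soft repulsion.  Includes an implicit membrane potential for 2D
    (membrane-anchored) systems, calibration of reaction rates against
    experimental dissociation constants, cluster and density-profile
    analyses, effective-valency and orientation observables, and
    Kirkwood-Buff slab estimation of interfacial tension with
    tension-inequality morphology classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
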