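Package: dsxchange
Title: Hybrid Monte Carlo / Langevin Simulation of Thiol-Disulfide Exchange
    Under Mechanical Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained force-clamp simulations of a five-cysteine
    immunoglobulin-like domain (I27*) coupled to a hybrid Monte Carlo /
    molecular dynamics scheme for spontaneous thiol-disulfide isomerization.
    Provides overdamped Langevin dynamics of a bead-per-residue chain under
    constant stretching force, in-stream first-passage detection of
    thiol-disulfide attack geometries, topology swaps accepted by a
    Metropolis criterion on locally minimized energies, a softcore
    sulfur-sulfur Lennard-Jones interaction that is finite at contact and
    exactly Lennard-Jones beyond a crossover distance, and the downstream
    analyses: sulfur-sulfur distance distributions, regioselectivity with
    bootstrap standard errors, attack-angle survival curves, unfolding
    statistics, loop principal component analysis, and Shrake-Rupley
    solvent-accessible surface area with Kolmogorov-Smirnov group
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
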