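Package: catchdmd
Title: Coarse-Grained Co-Assembly Simulation and Structural Analysis of
    Charge-Complementary Peptide Nanofibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the co-assembly of charge-complementary
    (CATCH-type) beta-sheet peptides. Provides an ideal beta-sheet bilayer
    constructor with prescribed strand spacing, inter-sheet gap and twist; an
    event-driven discontinuous molecular dynamics (DMD) engine over a
    four-bead-per-residue square-well peptide model with directional backbone
    hydrogen bonding and an Andersen-style ghost-collision thermostat;
    geometric analyses of assemblies (strand-axis twist, plane-fit inter-sheet
    distance, hydrogen-bond and salt-bridge detection, contact maps, Kabsch
    RMSD, secondary-structure aggregation); and graph-based assembly kinetics
    (oligomer, beta-sheet and beta-barrel tracking with transition detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
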