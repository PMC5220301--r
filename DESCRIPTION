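Package: dimerscope
Title: Prediction and Characterization of Weak-Affinity Protein Homodimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting and characterizing weak, transient protein
    homodimers of the kind formed by membrane-anchored small GTPases. Covers
    docked-pose clustering with empirical viability filters, residue
    co-evolution hotspot mapping from multiple sequence alignments,
    quantitative interface metrics (Shrake-Rupley solvent-accessible surface
    area and buried interface area, hydrogen bonds, hydrophobic contacts,
    salt bridges, pi-stacking, centre-of-mass distance and relative monomer
    orientation), potential-of-mean-force integration with standard-state
    dissociation constants and binding free energies, computational alanine
    scanning, and Ripley's K-function spatial statistics for nanocluster
    analysis of 2-D point patterns. Includes synthetic-data generators with
    known ground truth (ideal helical dimers with planted salt bridges,
    alignments with planted covarying column pairs, mean-force profiles of
    known well depth, clustered and random point patterns) so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
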