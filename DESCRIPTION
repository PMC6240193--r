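Package: mhc2lig
Title: MHC Class II Natural Ligand Prediction with Antigen Processing Context
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modelling of MHC class II in vitro binding affinity and
    mass-spectrometry eluted ligand data with a two-output shallow neural
    network that aligns a nine-residue binding core within each peptide.
    Includes burn-in restricted core search, balanced mixed-data online
    training, common-motif cross-validation partitioning, random-negative
    enrichment from a source proteome, encoding of ligand context residues
    that carry antigen processing signals, extraction and comparison of
    terminal processing footprint matrices, Kullback-Leibler logo matrices,
    ROC-based benchmark metrics, two T cell epitope benchmark protocols,
    and a synthetic-data generator that emulates the statistical structure
    of immunopeptidome data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
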