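Package: gridpocket
Title: Multi-Channel Voxel Descriptors and 3D Convolutional Prediction of
    Protein Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds four-channel voxel-grid descriptors of protein structures:
    a protein-solvent-protein cavity scan channel together with van der Waals,
    hydrogen-bond and Coulomb probe-energy channels computed from
    AutoDock-style atom types and partial charges read from PDBQT files.  A
    compact 3D convolutional neural network is trained on labelled 16 Angstrom
    sample blocks to recognise drug binding sites; sliding-window scanning,
    density-based clustering of positive blocks into ranked pocket centers,
    center-offset evaluation utilities and a deterministic synthetic-structure
    generator with planted cavities complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
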