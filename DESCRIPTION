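Package: rbmotif
Title: Ensemble Restricted Boltzmann Machines for Secondary-Structure
    Boundary Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains ensembles of spin-variable restricted Boltzmann machines
    (RBMs) on fixed-length amino-acid stretches at the start and end of
    alpha-helices and beta-sheets, consolidates the learned hidden units
    across independent training realizations by density-based clustering
    into an average RBM, decomposes that model into its 2^Nh hidden-state
    sequence modes with position-specific residue probability tables, and
    extracts an effective-hydrophobicity ordering of the amino acids from
    a principal component analysis of the learned weights.  Includes a DSSP
    parser and stretch extractor, exact small-model oracles (partition
    function, pseudo-log-likelihood, exact sequence generation), and
    planted-model synthetic data generators so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
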