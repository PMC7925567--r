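Package: coevppi
Title: Protein-Protein Interaction Prediction from Evolutionary Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds species-paired concatenated multiple sequence alignments,
    infers direct evolutionary couplings between residues by regularized
    pseudo-likelihood maximization of a Potts model, and turns the couplings
    into calibrated residue-contact and protein-interaction scores. Includes
    average product correction, EVcomplex-style score normalization, logistic
    regression contact classifiers (structure-free and structure-aware),
    minimum-atom distance maps and solvent accessibility from structures,
    docking restraint export, and a synthetic paired-Potts generator for
    end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    glmnet,
    Matrix,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
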