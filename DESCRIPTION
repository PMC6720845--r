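Package: domppi
Title: Domain-Based Prediction of Protein-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions (PPI) from protein domain
    content. Physicochemical properties (theoretical pI, instability index,
    aliphatic index, GRAVY, charge and atom counts, extinction coefficients)
    are computed directly from Pfam-style domain amino-acid sequences and,
    together with an encoded subcellular location, form a 20-dimensional
    feature vector per domain pair. An RBF-kernel support vector machine
    classifies domain pairs as interacting or not; the classifier's
    predicted-pair ratio is fused with a log-normalised domain-interaction
    score into a per-protein-pair probability, with lattice search over the
    fusion weights and a false-negative/false-positive balanced threshold
    selection. Includes a self-contained synthetic-data generator, repeated
    stratified cross-validation, confusion-matrix metrics (MCC, F1, ROC/AUC),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
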