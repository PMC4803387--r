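Package: plbpred
Title: Automatic Generation of Protein-Ligand Binding-Site Predictors
Version: 0.1.0
Authors@R:
    person("UTProt", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for building sequence-based protein-ligand
    binding-residue predictors from protein-ligand complex structures.
    Parses PDB files, extracts ligand-binding residues by atomic distance
    using an octree spatial index with covalent-ligand exclusion, removes
    sequence redundancy by greedy identity/coverage clustering, encodes
    residues as sliding-window PSSM feature vectors with terminal spacer
    flags, trains RBF-kernel support vector machines, single-hidden-layer
    neural networks and random forests, tunes hyperparameters by genetic
    algorithm or grid search against cross-validated AUC with a persistent
    evaluation cache, and reports ROC/AUC, MCC, sensitivity and
    specificity under stratified k-fold cross-validation. Ships
    deterministic fixture generators (toy complexes, sequence families,
    profiles, labeled feature sets) so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
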