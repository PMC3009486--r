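Package: mrsrf
Title: All-Pairs Robinson-Foulds Distance Matrices via a MapReduce-Style Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the t x t Robinson-Foulds (RF) distance matrix for a
    collection of phylogenetic trees using a two-phase map/shuffle/reduce
    decomposition over a global bipartition hash table, with grid
    partitioning of the matrix across simulated worker nodes. Includes a
    brute-force oracle for verification, run-block summarization of RF-rate
    matrices for Bayesian convergence assessment, seeded generators for
    random binary trees and run-structured collections, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
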