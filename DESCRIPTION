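Package: rnafitness
Title: Benchmarking Fitness Functions for RNA Secondary Structure Design
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing the fitness functions that guide RNA
    inverse folding (sequence design): structure representations and
    distances (base-pair distance, structural Hamming distance,
    Matthews-correlation agreement), free-energy, GC-controlled
    free-energy, structure-probability and ensemble-defect fitness
    evaluators, an adaptive random walk designer with base-pair
    preserving mutations, a synthetic design-puzzle generator based on
    suboptimal-structure sampling, and benchmark and ranking harnesses
    that measure solve rates under the unique-MFE correctness
    criterion.  Folding thermodynamics are delegated to a pluggable
    backend: an adapter to the ViennaRNA package (via its Python
    bindings) and a small self-contained reference energy model whose
    folding, partition function, base-pair probabilities and
    suboptimal enumeration are implemented with exact integer
    energies so that every downstream quantity can be verified against
    exhaustive enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python 3 with ViennaRNA bindings (only for the
    ViennaRNA backend)
Config/testthat/edition: 3
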