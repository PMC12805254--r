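Package: gpcrmoa
Title: Hierarchical Graph Modeling of Ligand-Induced GPCR Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a small molecule is a nonbinder, agonist, or
    antagonist of a G-protein-coupled receptor (GPCR) by modeling ligand
    recognition at an atomistic binding-site graph and propagating the
    interaction signal through an E(3)-equivariant graph network with
    cross- and self-attention over the receptor structure. Includes
    activation-geometry analyses (TM6/TM7 displacement signatures, Welch
    tests, axis-aligned split probes), consensus binding- and
    allosteric-site construction, scaffold-based dataset splitting,
    hierarchical multitask training with a false-negative-aware loss,
    confidence-based rescue at inference, attention-based
    interpretability, and a synthetic receptor and ligand generator with
    planted geometric and pharmacophoric structure for end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
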