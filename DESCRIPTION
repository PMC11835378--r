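Package: ccdtree
Title: Conditional Clade Distributions for Summarizing Posterior Tree Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tractable distributions over rooted binary tree topologies
    from posterior tree samples using conditional clade distributions (CCD).
    Three parametrizations are supported: CCD0 (observed clades, with clade
    split expansion and per-clade normalization), CCD1 (observed clade
    splits), and CCD2 (clade splits conditioned on the sibling clade).
    Dynamic programming on the clade graph yields tree probabilities,
    exact tree counts, entropy and effective topology counts, clade
    probabilities, and maximum a posteriori (MAP) summary trees. Classic
    point estimators (maximum clade credibility tree, greedy majority-rule
    consensus) and evaluation metrics for comparing tree distributions
    (mean absolute and relative error of tree probabilities, credible sets,
    top-tree rank, replicate precision, Robinson-Foulds distances) are
    included, together with synthetic-data generators for simulation
    studies and a command-line interface for summarizing tree files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
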