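Package: dollotree
Title: Tumor Phylogeny Inference from Single-Cell Data Under the Dollo(k) Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs tumor progression trees from noisy, incomplete
    single-cell mutation matrices under the Dollo(k) evolutionary model, in
    which every mutation is gained exactly once and may be lost at most k
    times. Inference maximizes the likelihood of the observed matrix under a
    false-negative/false-positive error model by an exact branch-and-bound
    search over conflict-free completions of the extended gain/loss matrix,
    followed by randomized subtree-prune-and-reattach hill climbing. Includes
    a clonal-tree simulator with deletion nodes and missing-entry noise, and
    ancestor-descendant / different-lineage accuracy measures for comparing
    inferred trees with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
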