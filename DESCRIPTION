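Package: ppinet
Title: Protein-Protein Interaction Network Inference from Protein Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers protein-protein interaction (PPI) networks from protein
    expression matrices (e.g. reverse-phase protein array panels) by running a
    battery of fourteen inference methods spanning correlation, partial
    correlation, regression and mutual information, filtering predictions by a
    Gaussian graphical model significance rule, benchmarking each method
    against a gold-standard interactome with direct and indirect (k-path)
    matching, and assembling per-condition consensus networks from the best
    performing methods. Includes validation against non-interacting and
    tissue-specific reference edge sets (overlap percentages, precision-recall
    curves, class tallies, gene-set enrichment), network topology analytics
    (minimum dominating sets, collective influence, colored non-induced motif
    counting with a rewiring null), and a Gaussian graphical model simulator
    that generates complete synthetic studies for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    corpcor,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ROCR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
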