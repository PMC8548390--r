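Package: heteroprot
Title: Inheritance-Pattern Analysis of Hybrid Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-level heterosis in a parent/parent/F1
    hybrid trio design. Detects differentially expressed proteins between
    genotypes with pairwise t-tests and Benjamini-Hochberg adjustment,
    classifies each protein's inheritance mode (additive, dominant,
    over-dominant, under-dominant) from hybrid/parent fold-change rules,
    computes mid-parent, over-high-parent and below-low-parent heterosis
    indices for measured traits, partitions the three pairwise DEP sets,
    tests term over-representation, clusters expression profiles by
    average-linkage on Euclidean distances, and converts qPCR Ct values to
    relative expression with the Livak 2^-ddCt method. A synthetic-data
    generator plants known inheritance patterns so every stage can be
    validated against ground truth.
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
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
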