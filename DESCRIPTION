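Package: clonearch
Title: Clonal Architectures, Branching Scores, and Genomic Instability in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize intra-tumor heterogeneity from inferred
    clonal phylogenies. Provides a rooted clone-tree data model with the Tree
    score branching statistic and a likelihood-weighted consensus over
    candidate phylogenies; a discrete-time Galton-Watson branching-process
    simulator of tumor growth with driver and passenger mutations; per-sample
    genomic-instability metrics and classes from mutation and copy-number
    segmentation tables; a neutral-evolution classifier based on the linear
    one-over-f cumulative variant-allele-frequency fit; one-tailed rank-sum
    enrichment tests of binary features against clonal and subclonal mutation
    burdens with per-tumor-type false-discovery-rate control; and a synthetic
    cohort generator so every stage can be exercised and validated without
    external data.
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
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
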