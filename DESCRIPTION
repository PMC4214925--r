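Package: trainmap
Title: Functional Enrichment Maps for Trained-Immunity Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for contrasting a training stimulus
    (such as beta-glucan) against a non-training comparator (such as LPS) in a
    two-factor expression experiment. Provides quantile normalization,
    signal-to-noise response profiling, k-means clustering of gene response
    profiles, per-gene factorial interaction tests with Benjamini-Hochberg
    correction, hypergeometric gene-set enrichment over merged GMT collections,
    and construction of a functional enrichment map whose edges carry the
    average of the Jaccard and overlap coefficients and whose components are
    labelled with Tarjan's algorithm. A synthetic-data generator with planted
    responder genes and planted gene sets makes every stage testable without
    access to raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
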