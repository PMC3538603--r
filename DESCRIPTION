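Package: nscarray
Title: Transcriptome Analysis of Growth-Factor-Deprived Neural Stem Cell
    Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis pipeline for three-condition microarray
    studies of neurosphere cultures under partial growth-factor
    deprivation: fold-change classification of log2 expression profiles,
    pairwise scatter summaries, UPGMA hierarchical clustering on
    one-minus-correlation distances, Gene Ontology over-representation
    testing with annotation back-propagation and Benjamini-Hochberg
    false-discovery-rate control, KEGG-style flat gene-set enrichment,
    and comparative-CT (delta-delta-Ct) quantification of RT-qPCR data
    with microarray concordance. Ships a seeded synthetic-data generator
    that emulates the study design (Ctr/C2/C4 samples, planted
    differential probes, planted term enrichment, triplicate Ct tables)
    so every stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
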