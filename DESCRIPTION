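Package: seedwords
Title: Seed-Site and Word Enrichment Analysis for miRNA Perturbation
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate microRNA targets from differential
    expression data by combining hierarchical seed-site counting
    (6mer, 7mer-m8, 7mer-1A and 8mer matches) with set-level enrichment
    tests, an unbiased k-mer overrepresentation analysis over a ranked
    list of 3'UTRs using mononucleotide-shuffle null distributions, a
    running-sum statistic and permutation false discovery rates, and
    position-specific scoring matrix scanning of promoter sequences for
    transcription-factor binding-site enrichment.  Ships a synthetic-data
    generator that plants seed sites and promoter motifs with known
    expression effects so every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
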