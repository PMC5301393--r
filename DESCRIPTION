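Package: p335typer
Title: Proteome-Based Classification and In Silico Typing of Lactococcal
    P335 Bacteriophages
Version: 0.1.0
Authors@R:
    person("P335", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify bacteriophages of the heterogeneous
    lactococcal P335 group into its four sub-groups (I-IV). Implements
    all-against-all Smith-Waterman protein comparison with bidirectional
    best-hit extraction, Markov clustering (MCL) of the resulting
    similarity graph into protein families, proteome-profile grouping of
    phages, adhesion-module (TMP-Dit-Tal-baseplate/RBP) architecture
    typing against a labelled reference panel, in silico single-pair and
    multiplex PCR typing with the published seven-pair primer panel and a
    CWPS strain-typing scheme, and efficiency-of-plaquing statistics for
    calcium-dependence and antibody-neutralisation assays. A synthetic
    data module generates phage genomes, plaque counts and host-range
    matrices with known ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
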