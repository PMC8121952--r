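Package: rssnet
Title: Regulatory Network Enrichment and Gene Prioritization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian integration of genome-wide association study (GWAS)
    summary statistics with cell-type- and tissue-specific transcription
    factor to target gene (TF-TG) regulatory networks. A network-induced
    spike-and-slab prior on SNP effects is combined with a multiple-SNP
    regression likelihood on single-SNP association statistics and linkage
    disequilibrium estimates. Mean-field variational inference over a
    hyper-parameter grid yields Bayes factors that test a network for
    enrichment of genetic associations, and posterior probabilities that
    prioritize trait-associated genes within enriched networks, with
    Bayesian model averaging across networks. Includes trans-regulation
    scoring to build context-specific networks from paired expression and
    chromatin accessibility summaries, harmonization of externally derived
    networks, a full synthetic-data generator (block-LD genotypes,
    network-induced and mis-specified effect models, phenotypes, single-SNP
    statistics), and the evaluation metrics used to benchmark enrichment and
    prioritization methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    methods,
    generics,
    ggplot2,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
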