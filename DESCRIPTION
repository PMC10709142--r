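Package: tfscape
Title: Integrative Analysis of Transcription-Factor-Driven Chromatin, Interactome and Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrating chromatin accessibility, transcription-factor
    binding, proteomics and clinical outcome data around a 2x2 perturbation
    design (transcription-factor overexpression crossed with hormone
    stimulation). Provides negative-binomial Wald contrast statistics and
    rule-based cluster assignment for genes and accessibility peaks,
    one-tailed permutation tests for genomic annotation-category and
    histone-mark-overlap enrichment, cumulative TSS-proximity enrichment
    curves with permutation envelopes, promoter-enhancer link construction by
    rank correlation within 500 kb and link-enrichment permutation tests,
    motif overrepresentation z-scores with continuity correction,
    super-enhancer identification by peak stitching and rank-curve cutoff,
    proximity-labeling (BioID) interactor filtering and bait-network set
    algebra, and gene-signature survival stratification with Kaplan-Meier and
    log-rank comparison. A synthetic-data module generates every input with
    planted, recoverable structure so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
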