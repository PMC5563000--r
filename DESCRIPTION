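Package: panstress
Title: Comparative Pangenomics and Stress Transcriptomics of Bacterial Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for separating stress-tolerant from
    stress-sensitive bacterial strains by comparative genomics and
    transcriptomics. Provides bit-score-ratio homology detection and Markov
    clustering of ortholog families, clade-specific single-copy gene
    discovery, reciprocal-best-hit ANI/AAI and identity-based genome
    distances with species delineation, concatenated maximum-parsimony
    phylogenies with gene-tree branch support, a parameterized short-read
    mapper with Baggerley's beta-binomial proportions test for two-condition
    differential expression, delta-delta-Ct qPCR validation, and MIC/MTC
    phenotype calling from dose-response growth curves. A seeded synthetic
    data generator emulates multi-strain gene sets evolved with gene
    gain/loss/duplication, overdispersed count libraries with spiked fold
    changes, consistent Ct tables, and sigmoidal growth-yield declines, so
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    Matrix,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
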