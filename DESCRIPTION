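Package: hervex
Title: Endogenous Retrovirus Expression Screening from Short-Read RNA-Seq
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, self-contained pipeline for screening human
    endogenous retrovirus (HERV) and exogenous viral sequence expression in
    short single-end RNA-seq reads. Provides quality filtering and host
    subtraction, seeded nucleotide alignment of screened reads against a
    viral reference set with hit-rate normalization, construction of a
    retroviral gene catalog (RVGC) by six-frame translated homology search
    against retroviral protein domains, dual-scheme (best and comprehensive)
    multi-mapping read counting with FPKM reporting, domain-level
    discrimination by hierarchical clustering with Fisher exact testing, and
    the group-comparison statistics used throughout (Z-test, Mann-Whitney U,
    Benjamini-Hochberg FDR, Yates chi-square, one-way ANOVA, Tukey HSD).
    A synthetic-data generator with recorded ground truth supports
    parameter-recovery and calibration testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
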