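Package: alleleseg
Title: Allele-Specific Block Segmentation of Functional Genomic Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Segments per-SNP allele-specific read counts from a phased
    diploid genome into blocks of symmetric, maternal-biased, or
    paternal-biased signal using a three-state hidden Markov model with
    binomial emissions and a tuning parameter that constrains exits from
    the biased states. Provides Baum-Welch fitting with constrained
    transition rows, Viterbi decoding, block-level binomial verification
    with Benjamini-Hochberg FDR control, a beta-binomial simulation and
    evaluation harness, saturation-based tuning of the transition
    parameter against transcription start sites, and a gene-annotation
    surrogate-truth benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    utils
LinkingTo:
    Rcpp
Suggests:
    glmmTMB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
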