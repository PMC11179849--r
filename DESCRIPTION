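Package: diploscan
Title: Haplotype-Resolved Diploid Genome Comparison and Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the two phases of a haplotype-resolved diploid genome
    assembly and links the variation to gene expression. Extracts SNPs, short
    indels and structural variants (>= 40 bp) from pairwise alignments or a
    built-in anchor aligner, classifies transposable-element annotations as
    heterozygous or homozygous insertions by reciprocal overlap with the
    deletion set, validates LTR-retrotransposon insertions by their target-site
    duplication and dates them from intra-element LTR divergence, predicts
    coding impact of variants on gene models, and tests allele-specific
    expression per gene and organ with a beta-binomial model under
    Benjamini-Hochberg FDR control. Ships a seeded synthetic diploid generator
    with truth files so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    broom,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
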