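Package: herbiscreen
Title: Mutation Triage and Resistance Quantification for UV-Mutagenesis Herbicide Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for forward-genetic herbicide-resistance
    screens in haploid plants. Implements the non-allelism candidate-SNP filter
    cascade (read-support window, alternative-allele fraction, UV-B mutation
    spectrum, subtraction against non-allelic lines), strand-aware codon-effect
    annotation from GFF3/FASTA, cross-mutant convergence ranking of recurrently
    mutated genes, four-parameter log-logistic dose-response fitting with
    IC50/LD100/resistance-index conventions, and MS/MS precursor-scan metabolite
    annotation by shared fragment ions and neutral-loss deltas. A seeded
    synthetic-cohort generator produces every input (genome, gene models,
    per-line variant sets with ground truth, growth tables, peak tables) for
    benchmarking and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
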