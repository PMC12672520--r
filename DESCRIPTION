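Package: pharmscape
Title: Pharmacogenomic Landscape Analysis of Drug-Response Variants in a Cohort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying the pharmacogenomic landscape of a sequenced
    cohort against a curated drug-response variant catalog. Reads cohort
    genotypes from VCF, estimates allele and genotype frequencies, compares
    them to reference-population frequencies with chi-square, Fisher exact and
    two-proportion Z tests plus odds ratios and multiple-testing control,
    profiles pairwise linkage disequilibrium by EM haplotype-frequency
    estimation from unphased genotypes, and scores gene-level cumulative
    allele probability (CAP) burden. Includes a seeded synthetic diploid
    cohort simulator (Hardy-Weinberg genotypes, configurable two-locus
    linkage disequilibrium, singleton injection, missingness) so every stage
    is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
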