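Package: varcis
Title: Variant Catalogs and cis-eQTL Mapping for Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for nucleotide-resolution variant
    catalogs and their regulatory impact in panels of fully inbred lines. Provides
    a seeded synthetic-data generator (reference genome, planted SNP/indel/complex
    variants with a controlled allele-frequency spectrum, paired short reads,
    transcript annotation, log2 expression with planted cis effects, and F1
    allele-specific counts); indel normalization and rule-based variant-type
    classification; vote-based genotyping by differential read alignment against
    candidate alleles; genomic-context statistics (SNP density around variants,
    adjacency-excess simulation, density correlations, linkage disequilibrium,
    TSS/TES profiles, coding consequences); multi-allelic cis-eQTL mapping by
    Kruskal-Wallis and rank-regression association with permutation-based
    per-transcript thresholds and an FDR operating point; and allelic-imbalance
    testing in reciprocal F1 crosses with exact binomial tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
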