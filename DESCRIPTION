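Package: hybridscope
Title: Allele-Specific Expression, Methylome and Transcriptome Integration
    for Hybrid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for dissecting parent-of-origin effects in F1
    hybrids profiled against both parental reference genomes. Selects
    parent-diagnostic SNPs from hard-filtered parental variant calls, pairs
    the two parental gene sets by reciprocal best hits, aggregates
    allele-resolved RNA-seq read counts per gene to test and classify
    homoeolog expression bias (subgenome dominance), calls context-resolved
    (CG/CHG/CHH) differentially methylated regions and cytosines from
    bisulfite cytosine reports with windowed Fisher tests, calls
    differentially expressed genes, and integrates the methylome and
    transcriptome through expression-bin methylation profiles, Spearman
    correlation, and E/M quadrant classification of genes that are both
    differentially expressed and differentially methylated. Ships a seeded
    synthetic hybrid-cross generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    DESeq2,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    SummarizedExperiment,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
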