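Package: caprapop
Title: Genomic Characterization of Goat Populations from SNP-Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for SNP-array based genomic
    characterization of goat (and other livestock) populations: PLINK
    PED/MAP text genotype input and output, call-rate/MAF/relatedness
    quality control with per-breed subsampling, per-breed expected and
    observed heterozygosity and Wright's FIS, identity-by-state and
    Reynolds genetic distances with bootstrapped neighbor-joining trees
    and classical multidimensional scaling, sliding-window runs of
    homozygosity (ROH) with ROH-based inbreeding (FROH) by length class,
    linkage-disequilibrium based effective population size via the Sved
    relation, two-group selection-signature scans (per-SNP FST and the
    ROH-incidence delta H-score) with top-quantile retention and gene
    interval mapping, heart-girth based body-weight prediction, and a
    Balding-Nichols multi-breed genotype simulator that provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    e1071,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
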