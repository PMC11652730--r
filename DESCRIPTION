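Package: invscape
Title: Detection and Characterization of Polymorphic Chromosomal Inversions
    from SNP Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for detecting polymorphic chromosomal inversions in
    multi-population SNP genotype data and testing hypotheses about their
    maintenance. Detection combines per-contig and local principal component
    analysis with multidimensional-scaling outlier windows, linkage
    disequilibrium block detection, and three-cluster karyotype genotyping
    with heterozygosity checks. Called inversions are characterized by
    arrangement frequencies, divergence-based age estimates, Hardy-Weinberg
    tests (including X-linked), latitudinal clines with minor-allele-frequency
    matched permutation nulls, mutation load (piN/piS) contrasts,
    odorant-receptor gene enrichment, and latent-factor ridge
    genotype-environment association. A Balding-Nichols cohort simulator with
    full ground truth exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
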