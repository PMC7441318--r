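Package: homdel
Title: Biallelic Deletion Analysis in Consanguineous Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and interpretation of homozygous (biallelic, copy
    number zero) deletions in consanguineous families genotyped on SNP
    arrays. Provides sliding-window runs-of-homozygosity calling measured
    in genetic distance, family-level consanguinity classification,
    multi-caller copy-number-variant consensus with rarity classification
    against a control catalog, carrier-based case/control burden testing
    with the exact one-sided hypergeometric tail, Monte-Carlo
    interval-randomization tests of deletion overlap with epigenomic
    annotation tracks (intensity peaks and ChromHMM-style state
    segmentations) on a marker-density-defined mappable genome, gene
    neighborhood and TAD-boundary annotation, and a gene-dropping
    pedigree simulator that generates genotypes, caller call sets and
    annotation tracks with known ground truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
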