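Package: tandemCNV
Title: Genotyping and Case-Control Association of a Tandem-Duplication
    Copy-Number Variant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotyping a two-unit tandem-duplication copy-number
    variant on chr12p13.31 (spanning SLC2A3) and testing deletion carriers for
    case-control association. Implements the structural-allele copy-ratio
    model, paralogue-ratio-test (PRT) gel normalization and three-class
    classification, a two-feature SNP-intensity (BAF/LRR) region caller,
    single-changepoint inference of NAHR crossover intervals from partial-PRT
    profiles, and stratified Mantel-Haenszel association with
    Robins-Breslow-Greenland confidence intervals and Woolf heterogeneity
    testing. A seeded synthetic-data generator produces cohorts, gel
    intensities, SNP intensity tracks and partial-PRT profiles with the
    statistical structure the analysis assumes, so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    graphics,
    IRanges,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
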