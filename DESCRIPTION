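Package: RAFcompare
Title: Cross-Population Comparison of Cancer Risk-Allele Frequencies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares genome-wide-association risk-allele frequencies between
    ancestral populations from curated SNP catalogs. Pools per-variant allele
    frequencies across reference databases (1000 Genomes, ALFA, gnomAD) with
    allele-count weights, computes odds-ratio-weighted frequencies, collapses
    variants in linkage disequilibrium under gene/functional-region/direction
    exclusion rules, and tests for population differences with one-tailed
    t-tests and Deming errors-in-variables regression against the identity
    line. Includes locus- and outlier-removal sensitivity re-analyses and a
    synthetic catalog generator for type-I-error, power, and parameter-recovery
    calibration of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
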