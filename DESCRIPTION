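Package: triokit
Title: Trio Genome Analysis: De Novo Variants, CNV Ensembles and Pedigree Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for father-mother-offspring trio genomes:
    de novo SNV/indel detection with a depth/allele-balance/genotype-quality
    filter cascade, callability-based germline mutation-rate estimation,
    two-caller CNV ensemble merging with reciprocal-overlap concordance,
    de novo CNV detection with depth-based parental re-genotyping,
    variant-density hotspot scanning, novelty and cross-population sharing
    classification, novel-insertion archaic-hominin set logic, and
    deterministic transmission-based trio phasing.  Includes a synthetic
    trio-genome generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
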