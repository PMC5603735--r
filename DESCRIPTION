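Package: wincurse
Title: Winner's Curse Correction for Post-Hoc Analysis of Gene-Based
    Rare-Variant Tests
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step gene-based rare-variant association testing for
    case-control studies with a bootstrap resampling correction for
    winner's curse in post-hoc single-marker statistics.  Step 1 applies a
    weighted burden or SKAT-type variance-component test to a set of
    variants; for significant genes, Step 2 computes per-variant minor
    allele frequency differences (or their squares), estimates the
    selection-induced bias of each statistic by stratified case-control
    bootstrap resampling against the out-of-bag residual sample, and
    subtracts the median bias with sign clamping.  Includes a simulation
    engine for case-control genotypes under configurable minor allele
    frequency and relative risk architectures, evaluation machinery for
    power, bias, mean squared error and variant-ranking metrics, and
    readers and writers for VCF, dosage, phenotype and gene-set files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
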