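Package: germreset
Title: Germline Epigenetic Resetting Analysis: X Reactivation and
    Methylome Erasure at Single-Cell and Tile Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying epigenetic resetting in primordial germ
    cells (PGCs): inference of embryonic sex from chrY single-copy gene
    expression, X-chromosome reactivation (XCR) evidence from expression
    dosage (female:male ratios, bootstrapped X:autosome ratios) and from
    allelic SNV read counts (biallelic calling, somatic XCI-escaper
    identification), and whole-genome bisulfite methylome analysis
    (coverage-weighted region and tile methylation, promoter CpG-class
    assignment, scaled gene metaprofiles, demethylation-escapee detection
    with transposable-element enrichment scoring). Includes a seeded
    synthetic-data generator with planted ground truth so every analysis
    is testable as a parameter-recovery problem.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
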