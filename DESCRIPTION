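Package: divassign
Title: Genotype Data Management, Quality Filtering and Population
    Assignment for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale toolkit for managing diploid biallelic SNP
    genotype datasets and assigning individuals to reference
    populations. Reads and writes PLINK text (ped/map), EIGENSTRAT and
    HapMap formats; curates duplicate markers by chromosome position;
    applies a configurable quality-filtering cascade (individual and
    marker call rates, exact Hardy-Weinberg equilibrium test, minor
    allele frequency); computes allele sharing distances with
    per-population nearest-neighbour summaries; estimates ancestry
    proportions by supervised clustering with a fixed-frequency EM
    algorithm using Laplace-smoothed reference allele frequencies;
    performs principal component analysis of genotype matrices with
    smartpca-style outputs; and evaluates threshold-based assignment via
    assignment-rate and misassignment-rate curves. A seeded
    Balding-Nichols simulator generates differentiated reference
    populations and admixed query individuals with known ancestry for
    validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
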