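Package: evoscan
Title: Desk-Scale Genome-Evolution Analyses for Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidyverse-native implementations of the light-weight computations
    used to characterise a newly assembled plant genome: fourfold-degenerate
    transversion (4DTv) statistics with an HKY-consistent distance correction
    for dating whole-genome duplications, LTR retrotransposon insertion-age
    dating via Jukes-Cantor distances, centromeric-satellite detection by
    tandem-repeat monomer clustering and density scanning, rule-based
    gene-family screening (homology plus Pfam-domain filters) with tandem
    gene-array detection, expression summaries (RPKM, fold changes, row
    z-scores, qPCR delta-delta-Ct), and assembly summary statistics (Nxx,
    completeness percentages, GC content). A seeded synthetic-data module
    generates every input format the pipeline consumes with recorded ground
    truth, so all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
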