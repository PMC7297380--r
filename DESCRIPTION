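Package: mipseqr
Title: Analysis of Molecular Inversion Probe Targeted Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for targeted sequencing panels built
    on molecular inversion probe (MIP) capture. Takes multiplexed paired-end
    reads through sample demultiplexing, overlap consensus merging,
    alignment, MIP-arm trimming, diallelic pileup genotyping, structural
    variant (inversion) and sex calling from probe read counts, per-MIP
    representation statistics, and per-sample QC reporting as CSV and HTML.
    Includes a truth-annotated synthetic data generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
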