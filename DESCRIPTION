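Package: mtduplex
Title: Dual-Strand Mitochondrial DNA Heteroplasmy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying low-frequency mitochondrial DNA (mtDNA)
    heteroplasmy from dual-strand amplicon sequencing. Two complementary
    primer pools interrogate the two strands of the circular mitochondrial
    genome independently; variants called on both strands are accepted as
    true variants while single-strand observations are rejected as DNA
    modification artifacts. The package provides a strand-resolved pileup
    simulator, a per-pool binomial variant caller, both-strand concordance
    filtering, homoplasmy/heteroplasmy and transition/transversion
    classification, simplified haplogroup assignment against a packaged
    mini-tree, recurrence ('hot-spot') detection across subjects and
    tissues, and cohort-level odds-ratio and Fisher exact statistics, with
    tidy tibble interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
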