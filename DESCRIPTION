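Package: varspectrum
Title: Variant-Spectrum Comparison of Re-Sequenced Case Cohorts Against
    Population Controls and Aggregate References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the spectrum of single-nucleotide variation observed in a
    re-sequenced case cohort against a genotype-level control population and an
    ExAC/gnomAD-style aggregate reference. Computes per-gene spectrum statistics
    (rare-variant counts at a minor-allele-frequency threshold, population-specific
    variant counts, concordantly damaging variant counts), tests them with a
    one-sided per-site allele-randomization permutation test and a one-sided
    reference-cohort simulation test, screens common variants with a
    two-proportion normal-approximation test and Hardy-Weinberg checks, and
    builds per-gene summary tables. Ships a synthetic-data generator that
    emulates two cohorts sharing common variants plus population-private rare
    variants under a neutral-like site-frequency spectrum, with X-linked genes
    and a tunable case rare-variant enrichment factor, so the whole pipeline is
    testable without external downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
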