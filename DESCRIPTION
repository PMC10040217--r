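Package: colocshuffle
Title: Permutation Tests for Genomic Co-Localization, IP-MS Enrichment, and
    Coverage Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies co-localization between genomic interval sets with a
    permutation test: comparison peaks are shuffled genome-wide with their
    length distribution preserved and assembly gaps/blacklisted regions
    excluded, yielding empirical p-values, Bonferroni-adjusted significance,
    and log2 fold enrichment of observed over expected base-pair overlap.
    Also scores immunoprecipitation mass-spectrometry spectral counts with
    per-protein Fisher exact tests and fold enrichment over a negative
    control, normalizes coverage tracks by background scaling over randomly
    sampled genomic regions, computes mean-signal metaprofiles around peak
    centers, and simulates genomes, co-localized peak sets, spectral-count
    tables, and condition-structured coverage tracks with planted effects
    for end-to-end validation. All interval data are plain tibbles in BED
    conventions (0-based, half-open).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
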