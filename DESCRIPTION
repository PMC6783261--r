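Package: tedyn
Title: Transposable Element Load Dynamics Under Sexual and Asexual
    Reproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of transposable
    element (TE) copy-number evolution in a constant-size haploid yeast
    population, with periodic sexual episodes, transposition-excision
    balance, copy-number selection with optional synergistic epistasis,
    and an unlinked excision-rate modifier allele that can spread by
    hitchhiking. Companion analysis tools cover the table-level
    statistics used in pooled-sequencing TE surveys: deduplication of
    insertion calls reported by multiple detectors, length-based
    classification of LTR retrotransposon insertions (full-length, solo
    LTR, truncated), read-fraction TE load, coverage residualisation,
    permutation ANOVA with a coverage nuisance covariate, and
    regression-based estimates of TE loss over experimental time.
    Synthetic-data generators reproduce the structure of an experimental
    evolution design (replicate sexual and asexual strains sampled every
    90 generations with coverage-dependent detection) so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
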