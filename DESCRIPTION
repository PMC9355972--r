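Package: sigsegment
Title: Regional Mutational Signature Assignment for Individual Somatic Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns individual somatic single-nucleotide variants to their
    cognate mutational signatures while accounting for the regional
    (non-uniform) activity of mutational processes along cancer genomes.
    Coordinate-sorted 96-channel mutation catalogs are segmented per
    chromosome by greedy merging under a modified Bayesian information
    criterion for a multinomial model; non-adjacent segments with similar
    trinucleotide spectra are merged into mutation clusters by the analogous
    criterion; per-cluster signature exposures are refit by
    expectation-maximization (or non-negative least squares) against a
    COSMIC-style signature matrix, and each mutation is assigned to the
    signature maximizing its posterior probability. Downstream statistics
    include an entropy-based permutation test of within-cluster concordance
    of external per-mutation signals (replication timing, cancer cell
    fraction), kataegis detection with per-signature Fisher enrichment, and
    pairwise Kolmogorov-Smirnov discordance of per-signature cancer cell
    fraction distributions. A seeded synthetic-genome generator provides
    ground-truth catalogs, signals and cancer cell fractions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    pracma,
    Biostrings,
    GenomicRanges,
    IRanges,
    vcfR,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
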