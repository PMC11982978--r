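Package: dsitescreen
Title: Analysis of Competitive Yeast Two-Hybrid Docking-Site Selection Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of pooled competitive selection
    screens of MAP kinase docking-site (D-site) peptide libraries read out by
    amplicon sequencing, as used to map ERK2 docking specificity and its
    rewiring by common-docking-site cancer mutations. Provides a synthetic
    screen generator (genotype-dependent occupancy-linked fitness, exponential
    competitive growth, multinomial read sampling, FASTQ emission), amplicon
    read counting against a library whitelist, enrichment-score estimation as
    the slope of log frequency change per population doubling, Z-score hit
    calling, lost/common/gained interactome comparison across kinase variants,
    short-linear-motif scanning and binomial positional-overrepresentation
    (probability logo) statistics, and four-parameter logistic IC50 fitting
    for competitive-inhibition dose-response data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
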