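Package: heataa
Title: Heat-Stress Expression Response and Protein Composition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a gene's transcriptional response to heat stress (the log2
    ratio of expression at 37 vs 22 degrees Celsius) to the encoded protein's
    amino-acid class composition and intrinsic-disorder content. Provides
    probe-level quality filtering and annotation filtering for microarray
    data, gene-level aggregation of expression, longest-isoform protein
    feature extraction (amino-acid frequencies, charged/polar/hydrophobic
    class fractions, GC content), windowed pairwise-energy intrinsic-disorder
    scoring, and a confound-controlled statistical battery (Spearman and
    partial Spearman correlations, Mann-Whitney comparisons, one-tailed
    binomial sign tests, Benjamini-Hochberg correction), stratified by
    subcellular compartment. Ships a synthetic-data generator with known
    feature-response couplings so that every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
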