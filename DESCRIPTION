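Package: strainshare
Title: Strain Sharing and Vertical Transmission Analysis for Vaginal
    Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether mothers and daughters carry the same
    vaginal bacteria. Implements Yue-Clayton theta compositional similarity
    with a binned permutation null for 16S phylotype profiles,
    reference-guided species binning of metagenomic contigs with
    coverage-based splitting into metagenome-assembled genomes (MAGs) and
    marker-based quality filtering, genome-wide pairwise strain comparison
    with coverage-overlap and identity thresholds for shared-strain calls,
    classification of the resulting sharing network by family relationship,
    and per-site per-year substitution-rate estimation under the hypothesis
    of vertical transmission at birth. A synthetic-data generator produces
    community-state-type structured cohorts and ancestor-derived genome
    pairs with known ground truth for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
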