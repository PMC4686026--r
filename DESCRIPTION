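Package: mthaplostat
Title: Mitochondrial Haplotype Diversity and Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tidy tools for mitochondrial haplotype population genetics from
    aligned sequence data: haplotype calling against a catalog of polymorphic-
    site profiles with a replication-based rule for accepting novel haplotypes,
    molecular diversity indices (haplotype frequencies with sampling standard
    deviations, unbiased gene diversity and its variance, nucleotide
    diversity), within- and between-population pairwise-difference summaries
    with Nei's corrected distance, one-level analysis of molecular variance
    (AMOVA) with variance components, Fst and a permutation test, and
    median-joining haplotype networks with median (Steiner) vectors. Includes
    a synthetic-data generator that reproduces a published countrywide lion
    sampling design so the full pipeline runs without any sequence download.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
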