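Package: cghpangenome
Title: Gene Presence/Absence Genotyping of Strains from Array-CGH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomic hybridization (CGH) on two-color microarrays
    measures, for each probe of a sequenced reference genome, the log2 ratio of
    a test strain's signal to the reference signal; low ratios indicate gene
    absence or divergence in the test strain. This package implements the full
    inference chain for such experiments: probe quality control against
    self-versus-self hybridizations and a per-probe ANOVA filter, a dynamic
    per-strain cutoff that converts log ratios into an estimated probability of
    presence (EPP) via a kernel density fit of the "present" mixture component,
    binary presence/absence calling at EPP > 95%, pan-genome partitioning into
    core, variable and reference-specific gene sets with pairwise overlap and
    dissimilarity statistics, a bootstrapped neighbour-joining dendrogram from
    the binary gene-content matrix, and a set-algebraic trait-association
    filter that tolerates one false negative or one false positive. A simulator
    of two-color CGH intensity tables with known gene-content truth drives
    validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
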