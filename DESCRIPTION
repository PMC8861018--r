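Package: dnmlineage
Title: De Novo Mutation Calling and Timing Classification in
    Three-Generation Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying germline de novo mutation (DNM) burden in
    three-generation sibships (F0 grandparents, F1 parents, F2 embryos)
    sequenced at moderate whole-genome depth.  Implements multi-rule
    single-nucleotide variant qualification (depth window, alternate-read
    support, site and mapping quality, tandem-repeat masking), pedigree-aware
    DNM calling with ancestral shared-variant removal, variant-allele-fraction
    classification of each DNM into the 2:2 (pre-meiotic, expected VAF 0.5)
    or 1:3 (unrepaired-mismatch, expected VAF 0.25) timing class,
    mutation-rate and fold-change arithmetic, strand-collapsed substitution
    spectra, Poisson genomic-window hotspot testing, coverage-based sex
    inference, and read-depth screening of structural-variant candidates.
    A seeded synthetic-pedigree generator emulates the study design (Poisson
    DNM counts per diet arm, binomial allele sampling at ~30x, configurable
    substitution spectra) so every stage is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
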