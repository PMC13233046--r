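Package: mutexcess
Title: Cross-Species Mutagen Sensitivity from Somatic SNV Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of mutagen-induced somatic
    mutation burden across mammalian species. Starting from per-sample
    somatic single-nucleotide-variant call sets of control and
    mutagen-treated fibroblast cultures, the package classifies variants
    into the 96 trinucleotide-context categories, rescales spectra to a
    common (human) genome trinucleotide composition, estimates per-species
    excess mutation frequencies (treated minus control, with bootstrap
    uncertainty), relates them to maximum lifespan, body mass and
    longevity quotient by linear regression with leave-one-out sensitivity
    analysis, and extracts de novo mutational signatures by non-negative
    matrix factorization with cosine matching against a reference catalog.
    A fully seeded synthetic-cohort generator emulates call-level output of
    single-molecule mutation sequencing so the whole pipeline is testable
    without external data.
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
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vctrs,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
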