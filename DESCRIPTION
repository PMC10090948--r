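Package: crossfeedSIP
Title: Protein Stable-Isotope Probing Analysis of Microbial Cross-Feeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers metabolite cross-feeding in two-species microbial
    co-cultures from 13C-labelling data. Provides isotopic-envelope arithmetic
    over peptide elemental compositions, in-silico tryptic digestion and
    species-unique peptide assignment against target and decoy proteomes,
    relative isotope abundance (RIA) estimation from MS1 envelopes with
    replicate-consistency filtering, a multiple linear regression attributing
    peptide labelling to individual amino acids with PCA over coefficient
    profiles, natural-isotope-abundance correction of GC-MS mass-isotopologue
    distributions, and a seeded synthetic co-culture generator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
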