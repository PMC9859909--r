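Package: karyoshift
Title: Chromosome Fission and Fusion Inference from Whole-Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers chromosome-scale rearrangements (fissions, fusions,
    translocations) from pairwise whole-genome alignment coordinates.
    Builds filtered synteny blocks, calls breakpoints where query
    chromosomes switch along a reference, classifies and polarizes events
    across a species set using an ancestral-karyotype outgroup,
    a randomization test and telomeric-repeat (TTAGG)n scanning, tests
    breakpoint regions for enrichment of coding sequence and transposable
    element classes by window resampling, and post-processes linkage-map
    marker tables for map-versus-assembly concordance. Ships a karyotype
    evolution simulator with a replayable ground-truth event log so the
    whole pipeline is testable without external data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
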