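Package: nucsig
Title: Construction and Refinement of Nuclear Localization and Export
    Signal Motif Catalogues
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds catalogues of nuclear localization signals (NLS) and
    nuclear export signals (NES) from labelled nuclear and non-nuclear
    protein sets. Starting from experimentally annotated seed motifs, an
    iterative in silico mutagenesis procedure (single-residue
    substitutions, then repeated specificity filtering and single-residue
    deletions) refines the seeds into a maximally sensitive catalogue
    that, by construction, matches no non-nuclear protein. Includes
    dataset preparation (low-complexity masking, length and redundancy
    filters, sequence-similarity family clustering), exact multi-pattern
    motif scanning with per-motif confidence statistics, physicochemical
    plausibility filters for NLS and NES, coverage and sharing reports,
    and a deterministic synthetic proteome generator with planted signals
    for end-to-end validation.
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
    igraph,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
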