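Package: repliconmap
Title: One-Versus-All Proteome Comparison Heat Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene-order-preserving matrices of best-hit percent
    identities between a seed bacterial proteome and every replicon
    (chromosome or plasmid) in a protein database, and renders them as
    threshold-filtered, sortable heat maps using max-sampling downscaling
    so that isolated high-identity cells remain visible at any zoom level.
    Includes parsers for GenBank flat files and a structured protein FASTA
    dialect, a round-trippable tab-delimited matrix format, an internal
    Smith-Waterman alignment backend with Karlin-Altschul E-values (plus an
    optional external BLAST+ backend), and a synthetic proteome evolution
    simulator for generating divergence, deletion, horizontal-transfer and
    fast-clock test fixtures.
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
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    scales,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
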