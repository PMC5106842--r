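Package: daspr
Title: Active-Site Profiling and Profile-Based Protein Database Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts active-site signatures from protein structures around
    curated key catalytic residues, aligns signature fragments across a protein
    set into an active-site profile of motif blocks (fragment-wise alignment,
    motif extension to the longest fragment, strict key-fragment consistency and
    overlap checks), builds a position-specific scoring matrix per motif with an
    exact background score distribution, and searches protein sequence databases
    by greedy longest-first sliding-window placement, combining per-motif
    p-values with the QFAST product-of-uniforms statistic into a single search
    score per sequence. Includes a deterministic synthetic-fixture generator
    (toy structures plus sequence databases with planted, partially conserved
    active sites) so the whole pipeline can be exercised without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
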