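Package: hdxmotif
Title: Differential HDX-MS Protection Mapping and Degenerate Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse differential hydrogen-deuterium exchange mass spectrometry
    (HDX-MS) peptide uptake tables to map protein-protein interaction interfaces:
    replicate uptake summaries with SEM envelopes, per-peptide differential
    uptake between an apo and a complex state, time-resolved protection calling,
    and reduction of overlapping protected peptides to minimal protected
    segments. A protected segment can then be generalised into a degenerate
    PROSITE-style sequence motif, scanned against proteomes with an analytic
    chance-expectation null model (plus a Monte Carlo check), and its
    cross-species conservation quantified through position frequency matrices,
    information content and consensus calls. A seeded forward simulator of HDX
    uptake kinetics, synthetic proteomes and ortholog sets makes the whole
    workflow testable without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
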