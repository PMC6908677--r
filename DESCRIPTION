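Package: seneschic
Title: Hi-C Analysis of 3D Genome Reorganization in Cellular Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binned Hi-C contact matrices through the
    lens of cellular senescence: iterative correction (ICE) of per-bin
    biases, observed/expected transformation, principal-component
    compartment scores with gene-density sign orientation, A/B compartment
    calling, per-bin compartment transition classification (including
    B-to-A-to-B reversals across three conditions), detection of
    senescence-associated heterochromatic foci (SAHF) and long-versus-short
    (LVS) contact scores, insulation-based TAD border strength and border
    calling with replicate-specificity classes, and the enrichment
    statistics that link genome reorganization to gene regulation
    (hypergeometric overlaps, pre-ranked gene-set enrichment with a
    permutation null, distance-window analysis around SAHF, signal-track
    summaries by compartmental category, and metagene profiles). A seeded
    synthetic-data generator plants compartment blocks, transitions, TADs,
    SAHF-like long-range structure, bin biases and coupled expression
    effects so every stage is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
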