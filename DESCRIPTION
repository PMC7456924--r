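Package: lsukit
Title: Coiled-Coil Dimer Modeling and Interactomics for the Arabidopsis LSU Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying dimerization and protein-protein interactions of
    the small coiled-coil LSU (RESPONSE TO LOW SULFUR) proteins of Arabidopsis
    thaliana. Builds ideal two-stranded parallel coiled-coil templates (Crick
    parameterization), threads sequence pairs over a grid of register shifts,
    scores models by leucine-zipper contacts, and predicts qualitative effects
    of point mutations on dimer stability. Scores tandem affinity purification
    mass spectrometry (TAP-MS) intensity tables with an abundance and
    relative-specificity statistic to call candidate partners, and ranks
    interaction-network hubs by their enrichment in LSU-interactome neighbors.
    A synthetic-data generator produces LSU-like sequences, intensity tables
    with planted partners, and networks with planted hubs so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    igraph,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
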