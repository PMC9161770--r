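Package: litkg
Title: Build, Enrich and Explore Literature-Derived Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-stage pipeline for turning predication-style literature
    extractions (subject-relation-object triples with per-entity confidence
    scores and supporting sentences) into a provenance-aware knowledge graph:
    ingestion of strict tab-separated dialects, confidence and occurrence
    filtration with dictionary-based entity normalization, deduplicated
    supporting-text and article metadata storage with journal impact factors,
    CUI-keyed integration of external relationship tables (gene-drug-disease-
    phenotype style sources) onto existing nodes, and export to a graph-database
    bulk-import CSV dialect. Includes an embedded query engine (direct evidence
    search, fuzzy entity search, depth-limited neighborhoods with per-layer
    filters, bounded-length simple-path search) and a seeded synthetic-fixture
    generator with ground-truth manifests.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
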