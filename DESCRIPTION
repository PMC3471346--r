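Package: semweave
Title: Semantic Integration of Quantitative Omics Data with RDF, SKOS and SPARQL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps quantitative omics observations (per-sample methylation and
    expression measurements) to an RDF model built from OBO Foundry terms,
    converts Gene Ontology hierarchies to SKOS concept schemes with
    annotation propagation along broader edges, materialises transcription
    factor coregulation networks to closure, merges the resulting semantic
    models on shared RefSeq URIs, and queries them with a built-in SPARQL
    subset engine. Includes set-logic analyses of drug-sensitivity contrasts
    (pathway counts, transcription factor candidates, Fisher exact
    enrichment) and a deterministic synthetic-data generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
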