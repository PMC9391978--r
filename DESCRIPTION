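Package: conceptkg
Title: Concept Knowledge Graphs from Annotated Document Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ranked, semantically grouped concept maps ("mental
    models") from concept-annotated document corpora, such as UMLS-annotated
    health-forum posts and PubMed abstracts. Documents are filtered to those
    mentioning a target condition, a document-level co-occurrence matrix is
    transformed with positive pointwise mutual information (PPMI) and reduced
    by truncated singular value decomposition, and cosine relatedness to the
    condition ranks the top concepts per semantic type. Results are
    materialized as a typed property graph (condition, semantic-type and
    concept nodes; isA, isRelatedTo and sameAs edges) exportable to GraphML
    or CSV, and two corpora can be compared concept-by-concept to classify
    convergent and divergent priorities with a mean +/- 2 standard-deviation
    rule. Includes a synthetic-corpus generator with planted topic structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
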