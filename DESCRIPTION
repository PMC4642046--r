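Package: bioevex
Title: Biomedical Event Extraction over Dependency-Parsed Interaction Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A corpus-agnostic pipeline for extracting biomedical events
    (typed, nested n-ary relations anchored to trigger words) from
    dependency-parsed text. Annotated corpora in the BioNLP Shared Task
    standoff format (.txt/.a1/.a2) are converted to and from a unified
    interaction-graph representation; the annotation rules of a corpus
    (entity, relation, event, modifier and prediction-target definitions
    with per-role and overall argument-count limits) are induced
    automatically from the data; and events are extracted by four
    consecutive sparse multiclass classification steps (entity, edge,
    unmerging, modifier) with scheme-driven candidate filtering, recall
    adjustment, and pluggable classifier back-ends including an
    always-correct oracle for component ablation. Includes a synthetic
    corpus generator, a micro-averaged event-level evaluator, and a
    GraphViz dot exporter for sentence annotation graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    Matrix,
    purrr,
    ranger,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
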