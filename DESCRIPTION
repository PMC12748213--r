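Package: graphragent
Title: Self-Correcting Agentic Graph Retrieval-Augmented Generation over
    Clinical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A property-graph framework for retrieval-augmented question
    answering over clinical knowledge graphs, built around an agentic
    control loop: multi-stage entity linking (exact, Levenshtein fuzzy,
    embedding-based), intent-driven graph retrieval with depth-bounded
    BFS neighborhoods and DFS path enumeration, dual-judge
    self-consistency sufficiency voting with score-based arbitration, a
    deterministic search-strategy optimizer, and confidence-scored answer
    synthesis with a warning-tagged fallback. Includes semi-automated
    knowledge-graph construction (chunking, extraction validation,
    CUI-first deduplication, evidence-weighted relation fusion, expert
    review set algebra, quality-control reporting), RAGAS-style
    evaluation metrics (faithfulness, context recall, answer relevancy),
    seeded mock language-model and embedding providers for fully offline
    deterministic runs, and a synthetic hepatology-like fixture
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
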