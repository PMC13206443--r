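Package: mealrec
Title: Constraint-Aware Meal Recommendation with Hybrid Retrieval and
    Knowledge-Graph Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-stage (refine-retrieve-rerank-reason) engine for
    translating fuzzy dietary queries into structured constraints,
    retrieving recipes with adaptively weighted hybrid sparse (Okapi
    BM25) and dense search plus food-knowledge-graph expansion with
    path-decay scoring, enforcing hard dietary constraints
    deterministically, scoring nutritional suitability against RDA
    targets with Atwater energy ratios and an energy-density penalty,
    and optionally verifying top candidates with a rule-based critic.
    Ships a seeded synthetic-data generator for recipe corpora, food
    graphs and stratified fuzzy-query benchmarks, and an evaluation
    harness (Recall@k, semantic recall, NDCG, constraint satisfaction
    rate) with component ablations.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
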