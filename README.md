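# mealrec

Constraint-aware meal recommendation from fuzzy natural-language
queries. A user asking for "something light but filling for dinner" is
implicitly asking for a calorie ceiling, a protein floor, and an
evening dish; a user with a nut allergy asking for "no nuts" must never
be shown a recipe containing peanuts. `mealrec` implements a four-stage
refine–retrieve–rerank–reason pipeline that makes both kinds of
requirement explicit and enforceable:

1. **Refine** — a deterministic rule/lexicon parser (with an
   embedding-centroid fallback) translates the query into a structured
   constraint set `C`: diet tags, mandatory/forbidden ingredients,
   per-meal macro bounds, course, and health goals.
2. **Retrieve** — hybrid sparse–dense search,

   `s_hybrid(q,r) = α(q)·s_dense(q,r) + (1−α(q))·s_bm25(q,r)`,

   where `α` is set per query class by a rule-based classifier
   (ingredient list 0.35, short dish name 0.20, intent markers 0.65,
   otherwise 0.50), plus food-knowledge-graph expansion: recipes
   reached from query concepts (e.g. *immune support → anti-inflammatory
   → turmeric/ginger/garlic → recipes*) receive
   `s_graph(q,r) = Σ_p λ^ℓ(p)` over simple paths `p`, with decay
   `λ = 0.9`. Candidates are pooled by `s_hybrid + β·s_graph`.
3. **Rerank** — a deterministic overlap cross-scorer (a pluggable slot
   for a cross-encoder) computes `s_cross`, and a hard rule engine
   discards every candidate violating a negative constraint, with
   category-aware exclusion ("nuts" vetoes "peanut butter").
4. **Reason** — nutritional suitability against per-meal RDA targets
   (`T_m = RDA_m/3`): capped adequacy `A_m = min(1, n_m/T_m)`, Atwater
   energy-ratio balance against a 30/40/30 protein/carb/fat split, and
   an energy-density penalty `exp(−κ(ED−τ))` above `τ` kcal/g, combined
   as `S_nutrition = 0.5·A_abs + 0.3·A_ratio + 0.2·A_ED`. Final ranking
   uses `Φ = s_cross + β·s_graph + γ·S_nutrition`; an optional strict
   mode runs a rule-based critic that re-checks ingredient lists *and*
   preparation-step text before anything is returned.

The package is aimed at researchers in nutritional informatics and
recommender-system evaluation: everything is deterministic and runs at
desk scale on seeded synthetic corpora, food graphs, and stratified
fuzzy-query benchmarks with planted ground-truth relevance, so retrieval
quality (Recall@5, SR@5, NDCG@5), constraint safety (CS-Rate) and
component ablations can be measured reproducibly without model weights
or external data.

## Worked example

```r
library(mealrec)

cfg    <- generator_config(corpus_size = 300, benchmark_size = 20, seed = 7)
corpus <- generate_corpus(cfg)
graph  <- generate_graph(corpus, cfg)
sparse <- build_sparse_index(corpus)
dense  <- build_dense_index(corpus)

refine_intent("something light but filling for dinner")
#> <constraint_set>
#>   macro calories: [-Inf, 600]
#>   macro protein: [20, Inf]
#>   course: dinner
```

"Light" became a 600 kcal ceiling, "filling" a 20 g protein floor, and
"dinner" a course constraint. A health-goal query then exercises the
whole pipeline:

```r
recommend("Immune boosting dinner", corpus, graph, sparse, dense,
          config = ranking_config(mode = "strict"))
#> <recommendation> query: "Immune boosting dinner" (strict mode, alpha=0.65)
#>   1. Basil Salmon Bake (r0169)  Phi=1.443  cross=0.33 graph=3.08 nutr=0.93
#>   2. Cilantro Cod Stew (r0208)  Phi=1.332  cross=0.22 graph=3.08 nutr=0.93
#>   3. Cumin Turkey Stew (r0182)  Phi=1.119  cross=0.22 graph=2.35 nutr=0.96
#>   4. Ginger Turkey Stew (r0250)  Phi=1.112  cross=0.22 graph=2.35 nutr=0.93
#>   5. Turmeric Beef Curry (r0061)  Phi=1.094  cross=0.22 graph=2.27 nutr=0.96
```

The query classifier detected an intent-rich query (`alpha = 0.65`,
favouring the dense signal), the graph expansion surfaced dinners
containing turmeric/ginger/garlic even though the query names none of
them (`graph` column), every candidate is a dinner (the course
constraint is hard), and the strict-mode critic verified ingredient
lists and step text before returning. Evaluation against a planted
benchmark:

```r
bench <- generate_benchmark(corpus, graph, cfg)
evaluate_benchmark(bench, corpus, graph, sparse, dense)
#> <eval_report full> 20 queries: R@5=0.258 SR@5=0.650 NDCG@5=0.287 CS-Rate=100.0%
```

CS-Rate = 100% is the designed behaviour: with correctly parsed
constraints the hard filter makes constraint violations in the top-5
impossible by construction.

A thin command-line wrapper covers the same flow
(`exec/mealrec generate-data|recommend|evaluate|ablate`); see the
vignette for the methods and parameter discussion.

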