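---
title: "Constraint-aware meal recommendation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-aware meal recommendation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealrec)
```

## The problem

Dietary queries are fuzzy ("something light but filling"), yet the cost
of a wrong recommendation is asymmetric: a slightly off-topic recipe is
an annoyance, a peanut-containing recipe shown to a nut-allergic user
is a safety failure. `mealrec` therefore separates the two kinds of
reasoning. Probabilistic signals (lexical and embedding similarity,
graph proximity, nutritional quality) *rank*; a deterministic rule
engine *vetoes*. Nothing a ranking signal does can resurrect a
candidate that violates a hard constraint.

The pipeline has four stages — refine, retrieve, rerank, reason — run
in a fixed order by `recommend()`: constraint extraction, adaptive
hybrid retrieval plus graph expansion, cross-scoring and hard
filtering, then nutrition scoring, final ranking and (optionally) a
critic pass. The hard filter runs before nutrition scoring and final
ranking; the critic runs only after ranking and can only remove.

## Stage 1: intent refinement

The primary parser is a deterministic phrase lexicon
(`default_intent_lexicon()`): each phrase found in the query
contributes a partial constraint set, fragments are merged, and
conflicting macro bounds resolve to the *intersection* — the tighter
bound wins, a safety-first choice ("light low calorie" yields the
500 kcal ceiling, not the 600 one). Negation patterns ("no nuts",
"dairy-free") add exclusions when the negated word is a known category
or ingredient. An unmatched query yields an empty constraint set rather
than an error, so downstream stages degrade to pure relevance ranking.

Two alternative extractors share the same output contract: an
embedding-centroid fallback (`semantic_fallback()`, nearest intent
centroid by cosine with ties broken lexicographically, returning empty
below a similarity threshold of 0.3 — a deliberately conservative value
so the fallback never invents constraints from a dissimilar query) and
a hook for an external LLM parser, which we treat as a pluggable
interface rather than a dependency: the rule parser and the fallback
are sufficient for reproducible desk-scale use, and the two modes are
mutually exclusive rather than reconciled.

## Stage 2: adaptive hybrid retrieval and graph expansion

Sparse scoring is Okapi BM25 (`k1 = 1.5`, `b = 0.75`, the conventional
settings) over the concatenated title + ingredients + steps. We use the
non-negative idf variant `log(1 + (N − df + 0.5)/(df + 0.5))` so scores
are exactly 0 without term overlap. Dense scoring is cosine similarity
of L2-normalized hashed bag-of-feature vectors (word tokens plus
boundary-padded character trigrams, 256 buckets, fixed hash seed). The
hashed embedder is deliberately weights-free and deterministic; any
sentence encoder honouring the unit-vector contract can be plugged into
`build_dense_index()`.

The two signals live on different scales (BM25 is unbounded, cosine is
in [−1, 1]), so both are min–max normalized to [0, 1] over the scored
pool before mixing — mixing raw scores would let BM25 magnitude swamp
the mixing weight. A constant signal normalizes to all-zeros (it
carries no ranking information). The mixing weight `α` comes from a
rule-based query classifier applied in priority order: comma-separated
lists of two or more food names (`α = 0.35`, lexical precision
matters), queries containing intent or health phrases (`α = 0.65`,
semantics matter), one-or-two-token dish/food names (`α = 0.20`),
otherwise `α = 0.50`. The operational definitions of "ingredient list"
and "short dish name" are ours: comma structure and token count against
the built-in lexicons; they reproduce the intended classifications on
the canonical examples ("chicken, rice, broccoli" / "pizza" / "Immune
boosting dinner").

Graph expansion bridges the vocabulary gap between abstract goals and
concrete ingredients. The food graph is typed — concept, ingredient and
recipe nodes; `promotes` (concept→concept/ingredient),
`has_ingredient` (concept→ingredient) and `contains_ingredient`
(ingredient→recipe) edges — and a recipe reachable from a query concept
scores the sum of `λ^ℓ` over all *simple* directed paths of at most
`max_hops` edges, `λ = 0.9`. Simple paths only, because the sum
diverges on cycles; `max_hops = 3` by default, because the canonical
bridge is concept → ingredient → recipe (2 edges) but concept → concept
→ ingredient → recipe chains (3 edges) are exactly the interesting
ones (immune support → anti-inflammatory → turmeric → recipe). Paths
from different query concepts are summed. Candidates are pooled by
`s_hybrid + β·s_graph` and truncated to `pool_size = 200`; a recipe
reachable only through the graph still enters the pool.

## Stage 3: cross-scoring and hard filtering

The shipped cross-scorer is the fraction of informative query tokens
(stopwords removed, plus graph-derived expansion terms for the query's
concepts) present in the recipe text — deterministic, auditable, and
exactly the interface a cross-encoder would occupy. The expansion terms
matter: they let "immune boosting" reward recipes that mention turmeric
without the query doing so.

Hard filtering is a conjunction of five clauses: no excluded ingredient
(after category expansion — "nuts" vetoes "peanut", and word-level
compound matching makes "peanut butter" match "peanut"), every
mandatory ingredient present (we treat inclusion as hard, consistent
with "mandatory"), course equality when constrained, per-meal macro
bounds against the nutrient vector, and diet-tag rules (vegan excludes
all animal-derived categories, etc., shipped as an editable ontology).
An excluded term that is neither a known category nor a known
ingredient triggers a configuration warning and is matched literally.
Every verdict records its violations with evidence, so filtering
decisions are serializable for audit.

## Nutritional suitability

Per-meal targets divide daily RDA values by `meals_per_day = 3`; the
shipped general-adult table (2000 kcal, 50 g protein, 70 g fat, 260 g
carbohydrate, 28 g fiber) is an editable configuration, not a clinical
recommendation. Adequacy is capped at 1 so moderate excess is not
penalized; the aggregate is the mean over all five nutrient dimensions
(calories and fiber included — the set is configurable). Energy ratios
use Atwater factors (4/4/9 kcal/g) with the *macro-derived* energy as
denominator rather than the stored calories field, which keeps the
ratios summing to 1 even when a record's calories disagree with its
macros; the balance score measures mean absolute deviation from a
30/40/30 protein/carb/fat split. Energy density `ED = kcal/g` is scored
1 up to `τ = 1.5` kcal/g — the conventional boundary between low and
medium energy density — and decays as `exp(−κ(ED − τ))` above it with
`κ = 1` (an e-fold per kcal/g), continuous at `τ`. The composite uses
weights (0.5, 0.3, 0.2): baseline adequacy first, macronutrient
structure second, satiety proxy last. A recipe with all macros zero has
undefined ratios; `nutrition_breakdown()` scores its balance component
0 rather than failing, while the low-level `energy_ratios()` raises an
error.

## Final ranking and the critic

Survivors are ranked by `Φ = s_cross + β·s_graph + γ·S_nutrition`,
ties broken by ascending recipe id for reproducibility. We default
`β = 0.3` and `γ = 0.2` so that semantic relevance remains the primary
signal and graph/nutrition act as boosts — with `s_cross` and
`S_nutrition` in [0, 1] and typical `s_graph` magnitudes of 1–3, larger
weights would let conceptual proximity dominate topical relevance.

Strict mode re-verifies the ranked list top-down with a rule-based
critic until `top_k` candidates pass: every hard constraint is
re-checked *and* the free-text preparation steps and title are scanned
for excluded-ingredient mentions ("garnish with crushed peanuts") and
for beverage wording against a lunch/dinner request (a smoothie is not
a dinner, however good its keyword match). Failures are removed and the
next-ranked survivors promoted, so strict mode can never return more
violating items than fast mode. Each verdict carries a natural-language
explanation citing the evidence checked — either the offending span or
the verified absences plus the relevant nutrient values.

## Synthetic data: what it emulates and what it does not

The generator (`generate_corpus()`, `generate_graph()`,
`generate_benchmark()`) emulates the *structure* of a recipe corpus
paired with a food knowledge graph and a stratified fuzzy-query
benchmark: recipes draw 4–8 ingredients from an ~80-ingredient lexicon
with per-course nutrient and mass ranges; the graph links 16 health
concepts to promoted ingredients and every ingredient to the recipes
containing it; benchmarks are stratified 30/26/24/20 across
health-goal, taste-craving, occasion-context and hybrid-complex
categories (largest-remainder rounding, so 150 queries split
45/39/36/30), with each query carrying ground-truth constraints and a
planted pool of 3–8 relevant recipes guaranteed to satisfy them.
A configurable fraction of recipes (default 20%) are planted
violators: open allergens in the ingredient list, allergens hidden only
in step text (invisible to ingredient-level filtering, catchable by the
critic), and beverage-style recipes labeled as main-meal courses.
Clean recipes avoid the allergen categories entirely so the violator
count is exact.

What passing tests on this data do **not** show: real recipe text is
noisier (synonyms, brand names, implied ingredients), real nutrient
vectors correlate with ingredients (ours are drawn from course-level
ranges), real relevance judgments are graded human pools rather than
planted sets, and a hashed embedder has no semantics beyond surface
overlap. Results on synthetic benchmarks certify the machinery —
determinism, constraint safety, metric arithmetic, ablation direction —
not absolute retrieval quality on real corpora.

## Evaluation choices

Semantic recall at k is defined as hit rate — 1 if the top-k contains
at least one relevant item — which matches pooled binary labeling;
plain Recall@k and NDCG@k (log2 discount, binary grades by default) are
also reported. CS-Rate is micro-averaged over top-5 items and checked
against the *ground-truth* constraints, not the parsed ones, so parsing
errors count against the system; a query with an empty result list
contributes 0 of k slots. These definitional choices (hit-rate SR@k,
k = 5 for CS-Rate) are documented here because alternatives exist and
results are not comparable across definitions. The ablation harness
re-runs the identical benchmark under four variants: full, graph
expansion removed, fixed `α = 0.7`, and hybrid score in place of the
cross-scorer.

## Determinism and problem sizes

Every source of randomness flows through explicit seeds
(`generator_config(seed = )`); generation, indexing, retrieval,
filtering and ranking are all deterministic given the seed and the
resolved configuration, and repeated runs are byte-identical. The test
suite exercises corpora of 25–500 recipes, benchmarks of 8–150
queries, and 250+ random graphs of at most 25 nodes cross-checked
against exhaustive path enumeration; these sizes give stable properties
while keeping a full run around a minute on a laptop.

## Limitations

- Constraint extraction is lexicon-bounded: paraphrases outside the
  shipped phrases (or centroid set) yield empty constraints, and the
  system then ranks without guardrails it was never given.
- The hard filter reasons over ingredient names, not preparation
  provenance; cross-contamination and certification-style rules
  (halal/kosher) are out of scope.
- Nutrition scoring is population-level (equal per-meal RDA split); no
  individualization by body mass, activity or biomarkers.
- The graph is curated, not learned; ingredient-level health claims are
  illustrative defaults, not medical assertions.
- The deterministic cross-scorer and hashed embedder are interfaces
  with honest but weak defaults; plugging in trained encoders changes
  ranking quality, not the surrounding guarantees.
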