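test_that("query classifier follows the documented priority rules", {
  expect_equal(classify_query("chicken, rice, broccoli"),
               "ingredient_list")
  expect_equal(classify_query("pizza"), "dish_name")
  expect_equal(classify_query("Immune boosting dinner"), "intent_marker")
  expect_equal(classify_query("what should I eat tonight"), "default")
  # intent markers outrank dish words, ingredient lists outrank both
  expect_equal(classify_query("healthy pizza"), "intent_marker")
  expect_equal(classify_query("salmon, spinach"), "ingredient_list")
})

test_that("adaptive alpha reproduces the four policy values", {
  expect_equal(compute_alpha("chicken, rice, broccoli"), 0.35)
  expect_equal(compute_alpha("pizza"), 0.20)
  expect_equal(compute_alpha("Immune boosting dinner"), 0.65)
  expect_equal(compute_alpha("what should I eat tonight"), 0.50)
  queries <- c("pizza", "salmon, rice", "healthy snack", "random words",
               "post-workout meal", "burger")
  for (q in queries)
    expect_true(compute_alpha(q) %in% c(0.35, 0.20, 0.65, 0.50))
})

test_that("BM25 scores equal an independent evaluation of the Okapi formula", {
  corpus <- fixture_corpus()
  index <- build_sparse_index(corpus)
  docs <- vapply(corpus$recipes, recipe_text, character(1))
  for (q in c("salmon turmeric", "lentil soup", "banana",
              "rice dinner")) {
    expect_equal(unname(bm25_scores(index, q)),
                 unname(brute_bm25(docs, q)), tolerance = 1e-12,
                 info = q)
  }
})

test_that("BM25 is zero without term overlap and positive with it", {
  corpus <- fixture_corpus()
  index <- build_sparse_index(corpus)
  expect_equal(unname(bm25_scores(index, "quasar")),
               rep(0, length(corpus)))
  one <- recipe_corpus(list(fixture_recipe(id = "only")))
  idx1 <- build_sparse_index(one)
  expect_gt(bm25_score(idx1, "chicken", "only"), 0)
  expect_error(bm25_score(index, "chicken", "nope"), "not indexed")
})

test_that("dense scores are cosine similarities of the hashed embeddings", {
  corpus <- fixture_corpus()
  index <- build_dense_index(corpus)
  # self-similarity: a query equal to the recipe text scores 1
  expect_equal(dense_score(index, recipe_text(get_recipe(corpus, "soup")),
                           "soup"), 1, tolerance = 1e-9)
  # any pair equals the brute-force dot product
  for (q in c("turmeric salmon", "berry smoothie", "soup")) {
    got <- dense_scores(index, q)
    for (id in corpus_ids(corpus))
      expect_equal(got[[id]],
                   brute_cosine(q, recipe_text(get_recipe(corpus, id))),
                   tolerance = 1e-9)
  }
})

test_that("disjoint vocabularies embed orthogonally", {
  expect_equal(brute_cosine("salmon dinner", "qqq zzz"), 0)
})

test_that("hybrid degenerate weights reduce to the single signal", {
  corpus <- fixture_corpus()
  ix <- fixture_indexes(corpus)
  q <- "turmeric salmon rice"
  dense_rank <- names(sort(-dense_scores(ix$dense, q)))
  sparse_rank <- names(sort(-bm25_scores(ix$sparse, q)))
  expect_equal(hybrid_retrieve(q, ix$sparse, ix$dense, k = 3,
                               alpha = 1)$id, dense_rank)
  expect_equal(hybrid_retrieve(q, ix$sparse, ix$dense, k = 3,
                               alpha = 0)$id, sparse_rank)
})

test_that("hybrid retrieval equals brute-force scoring on a random corpus", {
  corpus <- generate_corpus(generator_config(corpus_size = 30, seed = 9))
  ix <- fixture_indexes(corpus)
  for (q in c("ginger chicken dinner", "light lunch", "quinoa")) {
    got <- hybrid_retrieve(q, ix$sparse, ix$dense, k = 10, alpha = 0.5)
    sb <- bm25_scores(ix$sparse, q); sd <- dense_scores(ix$dense, q)
    nb <- if (diff(range(sb)) > 0) (sb - min(sb)) / diff(range(sb))
          else rep(0, length(sb))
    nd <- if (diff(range(sd)) > 0) (sd - min(sd)) / diff(range(sd))
          else rep(0, length(sd))
    sh <- 0.5 * nd + 0.5 * nb
    want <- names(sh)[order(-sh, names(sh))][1:10]
    expect_equal(got$id, want, info = q)
    expect_true(all(got$s_hybrid >= 0 & got$s_hybrid <= 1))
  }
})

test_that("hybrid retrieval is deterministic and respects k", {
  corpus <- generate_corpus(generator_config(corpus_size = 20, seed = 5))
  ix <- fixture_indexes(corpus)
  a <- hybrid_retrieve("spicy dinner", ix$sparse, ix$dense, k = 7)
  b <- hybrid_retrieve("spicy dinner", ix$sparse, ix$dense, k = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 7)
  expect_equal(nrow(hybrid_retrieve("x", ix$sparse, ix$dense, k = 100)),
               20)
})

test_that("index parameter invariants are enforced", {
  corpus <- fixture_corpus()
  expect_error(build_sparse_index(corpus, k1 = 0), "k1")
  expect_error(build_sparse_index(corpus, b = 1.2), "b")
})
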