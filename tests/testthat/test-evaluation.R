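test_that("recall@k follows the set-arithmetic definition", {
  ranked <- paste0("r", 1:10)
  expect_equal(recall_at_k(ranked, c("r1", "r3"), 5), 1)
  expect_equal(recall_at_k(ranked, c("r8", "r9"), 5), 0)
  expect_equal(recall_at_k(ranked, c("r1", "r2", "r8", "r9"), 5), 0.5)
  expect_true(is.na(recall_at_k(ranked, character(), 5)))
})

test_that("semantic recall is the top-k hit indicator", {
  ranked <- paste0("r", 1:10)
  expect_equal(semantic_recall_at_k(ranked, "r5", 5), 1)
  expect_equal(semantic_recall_at_k(ranked, "r6", 5), 0)
  set.seed(3)
  hits <- replicate(10, {
    rel <- sample(ranked, 3)
    semantic_recall_at_k(ranked, rel, 5)
  })
  expect_true(all(hits %in% c(0, 1)))
})

test_that("NDCG matches closed forms and an exhaustive permutation oracle", {
  expect_equal(ndcg_at_k(c("a", "b", "c"),
                         c(a = 3, b = 2, c = 1), 3), 1)
  # single relevant item at rank 2 of a binary list
  expect_equal(ndcg_at_k(c("x", "a"), c(a = 1), 5), 1 / log2(3))
  expect_equal(ndcg_at_k(c("x", "y"), c(a = 1), 2), 0)
  expect_equal(ndcg_at_k(c("x", "y"), numeric(), 2), 0)
  # every permutation of 4 graded items normalizes correctly
  grades <- c(a = 3, b = 2, c = 1, d = 0)
  perms <- list(c("a","b","c","d"), c("d","c","b","a"), c("b","a","d","c"),
                c("c","d","a","b"), c("a","d","b","c"), c("d","a","c","b"))
  idcg <- sum(c(3, 2, 1, 0) / log2(2:5))
  for (p in perms) {
    dcg <- sum(grades[p] / log2(2:5))
    expect_equal(ndcg_at_k(p, grades, 4), dcg / idcg, info = paste(p,
                                                        collapse = ""))
    expect_lte(ndcg_at_k(p, grades, 4), 1)
  }
})

test_that("CS-Rate counts compliant recommendations against ground truth", {
  corpus <- generate_corpus(generator_config(corpus_size = 60, seed = 47))
  viol <- attr(corpus, "violators")
  open <- viol$id[viol$flavor == "open_allergen"]
  C <- constraint_set(exclude = c("nuts", "dairy", "gluten",
                                  "shellfish"))
  clean <- setdiff(corpus_ids(corpus), viol$id)[1:4]
  mixed <- c(clean[1:3], open[1])   # exactly 3 of 4 compliant
  expect_equal(cs_rate(list(clean), list(C), corpus, k = 5), 100)
  got <- cs_rate(list(mixed), list(C), corpus, k = 5)
  expect_equal(got, 75)
  # micro-average over two queries: 4 + 3 compliant of 8 slots
  expect_equal(cs_rate(list(clean, mixed), list(C, C), corpus, k = 5),
               100 * 7 / 8)
  # empty result counts as 0 of k
  expect_equal(cs_rate(list(character()), list(C), corpus, k = 5), 0)
  # tightening a constraint never raises CS-Rate for a fixed result set
  C2 <- merge_constraints(C, constraint_set(course = "dinner"))
  expect_lte(cs_rate(list(mixed), list(C2), corpus, k = 5), got)
})

test_that("evaluation reports aggregate per-query metrics reproducibly", {
  cfg <- generator_config(corpus_size = 120, benchmark_size = 12,
                          seed = 53)
  corpus <- generate_corpus(cfg)
  graph <- generate_graph(corpus, cfg)
  bench <- generate_benchmark(corpus, graph, cfg)
  sparse <- build_sparse_index(corpus)
  dense <- build_dense_index(corpus)
  r1 <- evaluate_benchmark(bench, corpus, graph, sparse, dense)
  r2 <- evaluate_benchmark(bench, corpus, graph, sparse, dense)
  expect_equal(r1$per_query, r2$per_query)
  expect_equal(r1$sr, mean(r1$per_query$sr, na.rm = TRUE))
  expect_true(all(unlist(r1[c("recall", "sr", "ndcg")]) >= 0))
  expect_true(all(unlist(r1[c("recall", "sr", "ndcg")]) <= 1))
  expect_gte(r1$cs_rate, 0); expect_lte(r1$cs_rate, 100)
})

test_that("ablation variants alter exactly their targeted component", {
  cfg <- generator_config(corpus_size = 120, benchmark_size = 10,
                          seed = 59)
  corpus <- generate_corpus(cfg)
  graph <- generate_graph(corpus, cfg)
  bench <- generate_benchmark(corpus, graph, cfg)
  sparse <- build_sparse_index(corpus)
  dense <- build_dense_index(corpus)
  abl <- run_ablation(bench, corpus, graph, sparse, dense,
                      variants = c("full", "fixed_alpha"))
  expect_named(abl, c("full", "fixed_alpha"))
  # the fixed-alpha variant pins alpha = 0.7 for every query
  expect_true(all(abl$fixed_alpha$per_query$alpha == 0.7))
  expect_true(any(abl$full$per_query$alpha != 0.7))
  # the full variant is the standard pipeline run
  std <- evaluate_benchmark(bench, corpus, graph, sparse, dense)
  expect_equal(abl$full$sr, std$sr)
  expect_equal(abl$full$results, std$results)
  expect_error(run_ablation(bench, corpus, graph, sparse, dense,
                            variants = "no_such"), "variants")
})
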