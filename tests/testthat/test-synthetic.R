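test_that("corpus generation is seeded, sized and violation-counted", {
  cfg <- generator_config(corpus_size = 100, violation_rate = 0.2,
                          seed = 7)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_equal(length(c1), 100)
  for (id in corpus_ids(c1))
    expect_equal(unclass(get_recipe(c1, id)),
                 unclass(get_recipe(c2, id)))
  viol <- attr(c1, "violators")
  expect_equal(nrow(viol), 20)
  expect_true(all(viol$id %in% corpus_ids(c1)))
  expect_setequal(unique(viol$flavor),
                  c("open_allergen", "hidden_allergen",
                    "course_mismatch"))
  expect_length(generate_corpus(generator_config(corpus_size = 0)), 0)
})

test_that("planted open allergens really appear in the ingredient lists", {
  c1 <- generate_corpus(generator_config(corpus_size = 80, seed = 19))
  viol <- attr(c1, "violators")
  open <- viol[viol$flavor == "open_allergen", ]
  for (i in seq_len(nrow(open))) {
    ings <- get_recipe(c1, open$id[i])$ingredients
    expect_true(open$detail[i] %in% ings, info = open$id[i])
  }
  hidden <- viol[viol$flavor == "hidden_allergen", ]
  for (i in seq_len(nrow(hidden))) {
    r <- get_recipe(c1, hidden$id[i])
    expect_false(hidden$detail[i] %in% r$ingredients)
    expect_match(paste(r$steps, collapse = " "), hidden$detail[i])
  }
})

test_that("generated graphs are consistent with the corpus and seeded", {
  cfg <- generator_config(corpus_size = 40, seed = 29)
  corpus <- generate_corpus(cfg)
  g1 <- generate_graph(corpus, cfg)
  g2 <- generate_graph(corpus, cfg)
  expect_equal(igraph::as_data_frame(g1$igraph, "edges"),
               igraph::as_data_frame(g2$igraph, "edges"))
  ed <- igraph::as_data_frame(g1$igraph, "edges")
  ci <- ed[ed$type == "contains_ingredient", ]
  for (i in seq_len(nrow(ci)))
    expect_true(ci$from[i] %in% get_recipe(corpus, ci$to[i])$ingredients)
  # immune-support motif reaches turmeric recipes within 3 hops
  with_turmeric <- Filter(function(id)
    "turmeric" %in% get_recipe(corpus, id)$ingredients,
    corpus_ids(corpus))
  if (length(with_turmeric) > 0) {
    ge <- graph_expand(g1, "immune_system", max_len = 3)
    expect_true(all(with_turmeric %in% names(ge)))
  }
})

test_that("benchmark stratification uses largest-remainder rounding", {
  cfg <- generator_config(corpus_size = 250, benchmark_size = 150,
                          seed = 37)
  corpus <- generate_corpus(cfg)
  graph <- generate_graph(corpus, cfg)
  bench <- generate_benchmark(corpus, graph, cfg)
  cats <- table(vapply(unclass(bench), `[[`, character(1), "category"))
  expect_equal(as.integer(cats[c("health_goal", "taste_craving",
                                 "occasion_context", "hybrid_complex")]),
               c(45, 39, 36, 30))
  # odd sizes still sum exactly
  cfg2 <- generator_config(corpus_size = 250, benchmark_size = 17,
                           seed = 37)
  bench2 <- generate_benchmark(corpus, graph, cfg2)
  expect_length(bench2, 17)
})

test_that("benchmarks are deterministic and internally consistent", {
  cfg <- generator_config(corpus_size = 200, benchmark_size = 30,
                          seed = 41)
  corpus <- generate_corpus(cfg)
  graph <- generate_graph(corpus, cfg)
  b1 <- generate_benchmark(corpus, graph, cfg)
  b2 <- generate_benchmark(corpus, graph, cfg)
  expect_equal(unclass(b1), unclass(b2))
  for (bq in unclass(b1)) {
    expect_gte(length(bq$relevant), 1)
    expect_lte(length(bq$relevant), 8)
    expect_true(all(bq$relevant %in% corpus_ids(corpus)))
    # every planted relevant recipe passes the hard filter
    surv <- hard_filter(bq$relevant, bq$constraints, corpus)$survivors
    expect_equal(surv, bq$relevant, info = bq$query)
  }
})

test_that("benchmarks round-trip through JSONL", {
  cfg <- generator_config(corpus_size = 120, benchmark_size = 12,
                          seed = 43)
  corpus <- generate_corpus(cfg)
  graph <- generate_graph(corpus, cfg)
  bench <- generate_benchmark(corpus, graph, cfg)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_benchmark(bench, path)
  back <- read_benchmark(path)
  expect_length(back, length(bench))
  for (i in seq_along(bench)) {
    expect_equal(back[[i]]$query, bench[[i]]$query)
    expect_equal(back[[i]]$relevant, bench[[i]]$relevant)
    expect_equal(unclass(back[[i]]$constraints),
                 unclass(bench[[i]]$constraints))
  }
})

test_that("generator configuration invariants are enforced", {
  expect_error(generator_config(proportions = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(generator_config(violation_rate = 1.5), "violation_rate")
  expect_length(generate_benchmark(recipe_corpus(), empty_food_graph(),
                                   generator_config(corpus_size = 0,
                                                    benchmark_size = 0)),
                0)
})
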