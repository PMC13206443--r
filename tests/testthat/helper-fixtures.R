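# Small hand-authored fixtures shared across tests, built in code.

fixture_recipe <- function(id = "r1", title = "Garlic Chicken Stir Fry",
                           course = "dinner",
                           ingredients = c("chicken", "garlic", "rice",
                                           "broccoli"),
                           steps = c("Chop the garlic and broccoli.",
                                     "Cook the chicken with rice."),
                           total_mass_g = 450,
                           calories = 550, protein = 35, fat = 18,
                           carbohydrates = 60, fiber = 6) {
  recipe(id = id, title = title, course = course,
         ingredients = ingredients, steps = steps,
         total_mass_g = total_mass_g,
         nutrients = nutrient_vector(calories, protein, fat,
                                     carbohydrates, fiber))
}

# three-recipe corpus used in retrieval and filtering tests: a turmeric
# salmon dinner, a berry smoothie labeled dinner, and a plain soup
fixture_corpus <- function() {
  recipe_corpus(list(
    fixture_recipe(id = "salmon", title = "Turmeric Ginger Salmon Dinner",
                   ingredients = c("salmon", "turmeric", "ginger",
                                   "garlic", "rice"),
                   steps = c("Rub the salmon with turmeric and ginger.",
                             "Roast and serve over rice.")),
    fixture_recipe(id = "smoothie", title = "Berry Banana Smoothie",
                   course = "dinner",
                   ingredients = c("blueberry", "banana", "honey"),
                   steps = c("Blend the blueberry and banana with ice.",
                             "Pour the smoothie into a glass."),
                   total_mass_g = 300, calories = 320, protein = 8,
                   fat = 4, carbohydrates = 65, fiber = 5),
    fixture_recipe(id = "soup", title = "Carrot Lentil Soup",
                   course = "lunch",
                   ingredients = c("carrot", "lentil", "onion", "cumin"),
                   steps = c("Simmer the carrot and lentil.",
                             "Season with cumin."),
                   total_mass_g = 400, calories = 380, protein = 18,
                   fat = 8, carbohydrates = 55, fiber = 9)
  ))
}

# concept -> ingredient -> recipe graph over the fixture corpus,
# including the immune-support chain
fixture_graph <- function(corpus = fixture_corpus()) {
  nodes <- data.frame(
    name = c("immune_system", "anti_inflammatory",
             "turmeric", "ginger", "garlic", "lentil",
             corpus_ids(corpus)),
    type = c("concept", "concept",
             "ingredient", "ingredient", "ingredient", "ingredient",
             rep("recipe", length(corpus))),
    stringsAsFactors = FALSE)
  has_ing <- function(ing) {
    ids <- Filter(function(id) ing %in% get_recipe(corpus, id)$ingredients,
                  corpus_ids(corpus))
    if (length(ids) == 0) return(NULL)
    data.frame(from = ing, type = "contains_ingredient", to = ids,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    data.frame(from = "immune_system", type = "promotes",
               to = "anti_inflammatory", stringsAsFactors = FALSE),
    data.frame(from = "anti_inflammatory", type = "has_ingredient",
               to = c("turmeric", "ginger", "garlic"),
               stringsAsFactors = FALSE),
    do.call(rbind, Filter(Negate(is.null),
                          lapply(c("turmeric", "ginger", "garlic",
                                   "lentil"), has_ing))))
  food_graph(nodes, edges)
}

fixture_indexes <- function(corpus = fixture_corpus()) {
  list(sparse = build_sparse_index(corpus),
       dense = build_dense_index(corpus))
}

# brute-force cosine between two texts under the default embedder
brute_cosine <- function(a, b, dim = 256) {
  va <- as.numeric(embed_text(a, dim = dim))
  vb <- as.numeric(embed_text(b, dim = dim))
  sum(va * vb)
}

# independent Okapi BM25 evaluation from first principles (no index
# internals beyond raw tokenized docs)
brute_bm25 <- function(docs, q, k1 = 1.5, b = 0.75) {
  toks <- lapply(docs, function(d) tokenize(d)[[1]])
  N <- length(docs)
  avgdl <- mean(vapply(toks, length, integer(1)))
  qterms <- unique(tokenize(q)[[1]])
  vapply(seq_len(N), function(i) {
    s <- 0
    for (t in qterms) {
      df <- sum(vapply(toks, function(d) t %in% d, logical(1)))
      if (df == 0) next
      tf <- sum(toks[[i]] == t)
      if (tf == 0) next
      idf <- log(1 + (N - df + 0.5) / (df + 0.5))
      s <- s + idf * tf * (k1 + 1) /
        (tf + k1 * (1 - b + b * length(toks[[i]]) / avgdl))
    }
    s
  }, numeric(1))
}

# exhaustive simple-path enumeration by depth-first search over an edge
# list, independent of igraph
brute_paths <- function(edges, from, to, max_len) {
  out <- list()
  walk <- function(node, visited, len) {
    if (len > max_len) return()
    if (node == to && len > 0) {
      out[[length(out) + 1]] <<- len
      return()
    }
    nxt <- edges$to[edges$from == node]
    for (n in nxt) if (!n %in% visited) walk(n, c(visited, n), len + 1)
  }
  walk(from, from, 0)
  unlist(out) %||% integer()
}

`%||%` <- function(x, y) if (is.null(x)) y else x
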