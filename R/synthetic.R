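# Seeded synthetic data: recipe corpora with planted constraint
# violators, food knowledge graphs consistent with the corpus, and
# stratified fuzzy-query benchmarks with planted ground-truth relevance.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generator configuration
#'
#' Defaults mirror the benchmark's published structure: 150 queries
#' stratified 30% health-goal / 26% taste-craving / 24%
#' occasion-context / 20% hybrid-complex, over a 500-recipe corpus with
#' a 20% planted-violator rate.
#'
#' @param corpus_size Number of recipes.
#' @param benchmark_size Number of benchmark queries.
#' @param proportions Category proportions (named, sum 1).
#' @param violation_rate Fraction of recipes planted as violators.
#' @param seed Random seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(corpus_size = 500, benchmark_size = 150,
                             proportions = c(health_goal = 0.30,
                                             taste_craving = 0.26,
                                             occasion_context = 0.24,
                                             hybrid_complex = 0.20),
                             violation_rate = 0.2, seed = 1) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_config("proportions", "sum to 1")
  if (corpus_size < 0 || benchmark_size < 0)
    stop_config("sizes", "be >= 0")
  if (violation_rate < 0 || violation_rate > 1)
    stop_config("violation_rate", "lie in [0, 1]")
  structure(list(corpus_size = corpus_size,
                 benchmark_size = benchmark_size,
                 proportions = proportions,
                 violation_rate = violation_rate, seed = seed),
            class = "generator_config")
}

# ingredient pools for clean (non-violator) recipes: no nuts, dairy,
# gluten or shellfish, so the planted-violator count is exact
.clean_pools <- list(
  protein = c("chicken", "beef", "pork", "turkey", "salmon", "tuna",
              "cod", "egg", "tofu", "lentil", "chickpea", "black bean"),
  base    = c("rice", "quinoa", "oat", "corn", "buckwheat", "millet",
              "potato", "sweet potato"),
  veg     = c("broccoli", "spinach", "kale", "carrot", "onion", "garlic",
              "tomato", "bell pepper", "zucchini", "cauliflower",
              "mushroom", "cabbage", "cucumber", "celery", "beet",
              "pea", "green bean"),
  fruit   = c("apple", "banana", "orange", "lemon", "blueberry",
              "strawberry", "mango", "avocado", "pineapple", "grape"),
  spice   = c("turmeric", "ginger", "basil", "cilantro", "parsley",
              "cumin", "paprika", "chili", "cinnamon", "black pepper",
              "oregano", "rosemary", "thyme", "mint"),
  extra   = c("olive oil", "coconut oil", "sesame oil", "honey",
              "maple syrup")
)

.allergen_pool <- c("peanut", "almond", "walnut", "cashew", "milk",
                    "butter", "cheese", "cream", "yogurt", "wheat flour",
                    "bread", "pasta", "shrimp", "crab", "lobster")

.course_forms <- list(
  breakfast = c("bowl", "scramble", "porridge", "hash", "parfait"),
  lunch     = c("salad", "soup", "skillet", "plate", "bowl"),
  dinner    = c("stir fry", "curry", "bake", "roast", "stew"),
  snack     = c("bites", "mix", "sticks", "cups"),
  dessert   = c("pudding", "mousse", "sorbet", "fruit salad")
)

# per-course plausible nutrient and mass ranges (kcal, g)
.course_ranges <- list(
  breakfast = list(cal = c(250, 550), prot = c(8, 25), fat = c(8, 25),
                   carb = c(30, 70), fib = c(2, 8), mass = c(200, 450)),
  lunch     = list(cal = c(400, 750), prot = c(15, 40), fat = c(10, 30),
                   carb = c(40, 90), fib = c(3, 10), mass = c(300, 600)),
  dinner    = list(cal = c(450, 850), prot = c(20, 50), fat = c(12, 35),
                   carb = c(40, 100), fib = c(3, 12), mass = c(350, 700)),
  snack     = list(cal = c(100, 350), prot = c(3, 15), fat = c(4, 18),
                   carb = c(15, 45), fib = c(1, 6), mass = c(80, 250)),
  dessert   = list(cal = c(200, 600), prot = c(3, 10), fat = c(8, 30),
                   carb = c(30, 80), fib = c(1, 4), mass = c(100, 300))
)

title_case <- function(x) {
  gsub("\\b([a-z])", "\\U\\1", x, perl = TRUE)
}

make_recipe <- function(i, course) {
  rg <- .course_ranges[[course]]
  main <- sample(.clean_pools$protein, 1)
  base <- sample(.clean_pools$base, 1)
  vegs <- sample(.clean_pools$veg, sample(2:4, 1))
  spices <- sample(.clean_pools$spice, sample(1:3, 1))
  extras <- if (stats::runif(1) < 0.5) sample(.clean_pools$extra, 1)
            else character()
  fruit <- if (course %in% c("breakfast", "snack", "dessert"))
    sample(.clean_pools$fruit, sample(1:2, 1)) else character()
  ingredients <- unique(c(main, base, vegs, spices, extras, fruit))
  form <- sample(.course_forms[[course]], 1)
  title <- title_case(paste(spices[1], main, form))
  steps <- c(
    sprintf("Chop the %s and %s.", vegs[1], vegs[2]),
    sprintf("Cook the %s with %s until done.", main, base),
    sprintf("Season with %s and serve.", paste(spices, collapse = " and "))
  )
  recipe(id = sprintf("r%04d", i), title = title, course = course,
         ingredients = ingredients, steps = steps,
         total_mass_g = round(stats::runif(1, rg$mass[1], rg$mass[2])),
         nutrients = nutrient_vector(
           calories = round(stats::runif(1, rg$cal[1], rg$cal[2])),
           protein = round(stats::runif(1, rg$prot[1], rg$prot[2]), 1),
           fat = round(stats::runif(1, rg$fat[1], rg$fat[2]), 1),
           carbohydrates = round(stats::runif(1, rg$carb[1], rg$carb[2]), 1),
           fiber = round(stats::runif(1, rg$fib[1], rg$fib[2]), 1)))
}

#' Generate a synthetic recipe corpus
#'
#' Seeded corpus with ingredients from the built-in lexicon, per-course
#' nutrient and mass ranges, and `round(size * violation_rate)` planted
#' violators: recipes carrying an allergen in the ingredient list, an
#' allergen hidden only in the preparation steps, or beverage-style
#' content labeled as a main-meal course. Violators are flagged in the
#' corpus's `violators` attribute (id, flavor, detail).
#'
#' @param cfg A `generator_config`.
#' @return A `recipe_corpus` with a `violators` attribute.
#' @export
generate_corpus <- function(cfg = generator_config()) {
  n <- cfg$corpus_size
  if (n == 0) {
    out <- recipe_corpus()
    attr(out, "violators") <- data.frame(id = character(),
                                         flavor = character(),
                                         detail = character(),
                                         stringsAsFactors = FALSE)
    return(out)
  }
  with_seed(cfg$seed, {
    courses <- sample(.courses, n, replace = TRUE,
                      prob = c(0.2, 0.25, 0.3, 0.15, 0.1))
    recipes <- lapply(seq_len(n), function(i) make_recipe(i, courses[i]))
    n_viol <- round(n * cfg$violation_rate)
    viol_idx <- if (n_viol > 0) sort(sample(n, n_viol)) else integer()
    # violator mix: 3/5 open allergen, 1/5 hidden-in-steps allergen,
    # 1/5 beverage-course mismatch
    vrec <- vector("list", n_viol)
    for (j in seq_along(viol_idx)) {
      i <- viol_idx[j]
      flavor <- if (j %% 5 %in% c(1, 2, 3)) "open_allergen"
                else if (j %% 5 == 4) "hidden_allergen"
                else "course_mismatch"
      r <- recipes[[i]]
      if (flavor == "open_allergen") {
        allergen <- sample(.allergen_pool, 1)
        r$ingredients <- unique(c(r$ingredients, allergen))
        r$steps <- c(r$steps, sprintf("Fold in the %s.", allergen))
        detail <- allergen
      } else if (flavor == "hidden_allergen") {
        allergen <- sample(c("peanut", "almond", "walnut", "butter",
                             "cream"), 1)
        r$steps <- c(r$steps, if (allergen %in% c("butter", "cream"))
          sprintf("Finish with a swirl of %s before serving.", allergen)
          else sprintf("Garnish with crushed %ss before serving.",
                       allergen))
        detail <- allergen
      } else {
        course <- sample(c("lunch", "dinner"), 1)
        fruit <- sample(.clean_pools$fruit, 2)
        r$course <- course
        r$title <- title_case(paste(fruit[1], "smoothie"))
        r$steps <- c(sprintf("Blend the %s and %s with ice.",
                             fruit[1], fruit[2]),
                     "Pour the smoothie into a tall glass.")
        r$ingredients <- unique(c(fruit, "honey", "banana"))
        detail <- paste0("beverage labeled ", course)
      }
      recipes[[i]] <- r
      vrec[[j]] <- data.frame(id = r$id, flavor = flavor,
                              detail = detail, stringsAsFactors = FALSE)
    }
    out <- recipe_corpus(recipes)
    attr(out, "violators") <- if (n_viol > 0) do.call(rbind, vrec)
      else data.frame(id = character(), flavor = character(),
                      detail = character(), stringsAsFactors = FALSE)
    out
  })
}

#' Generate a food knowledge graph for a corpus
#'
#' Concept layer from [health_concepts()] (promotes edges between
#' concepts, has_ingredient edges to promoted ingredients), ingredient
#' nodes for every ingredient in the corpus, and a contains_ingredient
#' edge to every recipe actually containing that ingredient. Includes
#' the immune_system -> anti_inflammatory -> turmeric/ginger/garlic
#' chain. Deterministic given the corpus.
#'
#' @param corpus A `recipe_corpus`.
#' @param cfg A `generator_config` (unused fields ignored).
#' @return A `food_graph`.
#' @export
generate_graph <- function(corpus, cfg = generator_config()) {
  hc <- health_concepts()
  ingredients <- sort(unique(c(
    unlist(lapply(corpus$recipes, `[[`, "ingredients"), use.names = FALSE),
    unlist(lapply(hc, `[[`, "ingredients"), use.names = FALSE))))
  nodes <- rbind(
    data.frame(name = names(hc), type = "concept",
               stringsAsFactors = FALSE),
    data.frame(name = ingredients, type = "ingredient",
               stringsAsFactors = FALSE),
    data.frame(name = corpus_ids(corpus), type = "recipe",
               stringsAsFactors = FALSE))
  edges <- list()
  for (cpt in names(hc)) {
    for (tgt in hc[[cpt]]$promotes)
      edges[[length(edges) + 1]] <- c(cpt, "promotes", tgt)
    for (ing in hc[[cpt]]$ingredients)
      edges[[length(edges) + 1]] <- c(cpt, "has_ingredient", ing)
  }
  for (r in corpus$recipes) {
    for (ing in r$ingredients)
      edges[[length(edges) + 1]] <- c(ing, "contains_ingredient", r$id)
  }
  ed <- if (length(edges) > 0)
    data.frame(from = vapply(edges, `[`, character(1), 1),
               type = vapply(edges, `[`, character(1), 2),
               to = vapply(edges, `[`, character(1), 3),
               stringsAsFactors = FALSE)
    else data.frame(from = character(), type = character(),
                    to = character())
  food_graph(nodes, ed)
}

# --- fast vectorized constraint masks for the generator --------------------

precompute_corpus <- function(corpus) {
  list(
    ids = corpus_ids(corpus),
    course = vapply(corpus$recipes, `[[`, character(1), "course"),
    nutrients = t(vapply(corpus$recipes, `[[`, numeric(5), "nutrients")),
    ing_full = lapply(corpus$recipes, `[[`, "ingredients"),
    ing_terms = lapply(corpus$recipes, function(r)
      unique(c(r$ingredients,
               unlist(strsplit(r$ingredients, " ", fixed = TRUE),
                      use.names = FALSE))))
  )
}

term_mask <- function(pre, term) {
  if (!grepl(" ", term)) {
    vapply(pre$ing_terms, function(tt) term %in% tt, logical(1))
  } else {
    vapply(pre$ing_full, function(ings)
      any(vapply(ings, function(ing) term_matches_ingredient(term, ing),
                 logical(1))), logical(1))
  }
}

satisfies_mask <- function(pre, C, ontology) {
  ok <- rep(TRUE, length(pre$ids))
  for (t in C$exclude)
    for (term in expand_exclusion_terms(t, ontology))
      ok <- ok & !term_mask(pre, term)
  for (tag in C$diet_tags) {
    cats <- ontology$diet_rules[[tag]]
    for (term in unique(unlist(ontology$categories[cats],
                               use.names = FALSE)))
      ok <- ok & !term_mask(pre, term)
  }
  for (t in C$include) ok <- ok & term_mask(pre, t)
  if (!is.null(C$course)) ok <- ok & (pre$course == C$course)
  for (nm in names(C$macro)) {
    b <- C$macro[[nm]]
    v <- pre$nutrients[, nm]
    if (!is.null(b$min)) ok <- ok & (v >= b$min)
    if (!is.null(b$max)) ok <- ok & (v <= b$max)
  }
  ok
}

largest_remainder <- function(total, proportions) {
  raw <- total * proportions
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# goal concept -> query phrase used in health-goal templates
.goal_phrases <- c(
  immune_system   = "immune boosting",
  muscle_building = "muscle building",
  muscle_recovery = "post workout",
  weight_loss     = "weight loss",
  heart_health    = "heart healthy",
  gut_health      = "gut health",
  energy_boost    = "energizing",
  brain_health    = "brain food",
  iron_rich       = "iron rich"
)

concept_ingredients <- function(concept, hc = health_concepts()) {
  seen <- character(); queue <- concept; out <- character()
  while (length(queue) > 0) {
    c0 <- queue[1]; queue <- queue[-1]
    if (c0 %in% seen || is.null(hc[[c0]])) next
    seen <- c(seen, c0)
    out <- c(out, hc[[c0]]$ingredients)
    queue <- c(queue, hc[[c0]]$promotes)
  }
  unique(out)
}

# planted relevance pools default to 3-8 recipes per query, fewer only
# when the corpus offers fewer satisfying matches
pick_relevant <- function(pre, mask) {
  found <- pre$ids[mask]
  if (length(found) == 0) return(character())
  sort(sample(found, min(sample(3:8, 1), length(found))))
}

#' Generate a stratified fuzzy-query benchmark
#'
#' Queries are built from per-category templates; category counts follow
#' the configured proportions with largest-remainder rounding so they
#' sum exactly to `benchmark_size`. Each query carries its ground-truth
#' constraint set and a planted relevant-recipe set: every relevant
#' recipe satisfies the ground truth (checkable with [hard_filter()])
#' and carries the query's topical signal (e.g. a goal-promoted
#' ingredient), with 3-8 relevant recipes per query where the corpus
#' allows.
#'
#' @param corpus A `recipe_corpus`.
#' @param graph A `food_graph` over the corpus.
#' @param cfg A `generator_config`.
#' @param ontology Ingredient ontology used for constraint checks.
#' @return List of class `benchmark`; each element has `query`,
#'   `category`, `constraints` and `relevant`.
#' @export
generate_benchmark <- function(corpus, graph, cfg = generator_config(),
                               ontology = default_ontology()) {
  counts <- largest_remainder(cfg$benchmark_size, cfg$proportions)
  if (cfg$benchmark_size == 0 || length(corpus) == 0) {
    out <- list()
    class(out) <- "benchmark"
    return(out)
  }
  pre <- precompute_corpus(corpus)
  queries <- list()
  with_seed(cfg$seed + 1, {
    make_health <- function() {
      for (attempt in 1:50) {
        goal <- sample(names(.goal_phrases), 1)
        course <- sample(c("lunch", "dinner", "breakfast"), 1)
        C <- constraint_set(course = course, health_goals = goal)
        sig <- Reduce(`|`, lapply(concept_ingredients(goal), function(t)
          term_mask(pre, t)))
        mask <- satisfies_mask(pre, C, ontology) & sig
        if (sum(mask) >= 1) {
          tmpl <- sample(c("%s %s", "%s meal for %s",
                           "need something %s for %s"), 1)
          q <- sprintf(tmpl, .goal_phrases[[goal]], course)
          return(list(query = q, category = "health_goal",
                      constraints = C,
                      relevant = pick_relevant(pre, mask)))
        }
      }
      # deterministic fallback: drop the course constraint
      goal <- names(.goal_phrases)[1]
      C <- constraint_set(health_goals = goal)
      sig <- Reduce(`|`, lapply(concept_ingredients(goal), function(t)
        term_mask(pre, t)))
      list(query = paste(.goal_phrases[[goal]], "meal"),
           category = "health_goal", constraints = C,
           relevant = pick_relevant(pre, sig))
    }
    make_taste <- function() {
      for (attempt in 1:50) {
        taste <- sample(names(.taste_map), 1)
        ing <- .taste_map[[taste]]
        C <- constraint_set(include = ing)
        mask <- satisfies_mask(pre, C, ontology)
        if (sum(mask) >= 1) {
          q <- sprintf(sample(c("something %s", "craving something %s",
                                "%s food please"), 1), taste)
          return(list(query = q, category = "taste_craving",
                      constraints = C,
                      relevant = pick_relevant(pre, mask)))
        }
      }
      make_occasion()
    }
    make_occasion <- function() {
      for (attempt in 1:50) {
        course <- sample(c("lunch", "dinner", "breakfast"), 1)
        kind <- sample(c("quick", "family", "light"), 1)
        C <- switch(kind,
          quick = constraint_set(course = course,
                                 health_goals = "quick_meal"),
          family = constraint_set(course = course,
                                  health_goals = "family_friendly"),
          light = constraint_set(course = course,
                                 macro = list(calories = list(max = 600))))
        sig <- if (kind == "light") rep(TRUE, length(pre$ids))
          else Reduce(`|`, lapply(concept_ingredients(kind_concept(kind)),
                                  function(t) term_mask(pre, t)))
        mask <- satisfies_mask(pre, C, ontology) & sig
        if (sum(mask) >= 1) {
          q <- sprintf("%s %s", kind, course)
          return(list(query = q, category = "occasion_context",
                      constraints = C,
                      relevant = pick_relevant(pre, mask)))
        }
      }
      stop("cannot plant an occasion query on this corpus", call. = FALSE)
    }
    kind_concept <- function(kind)
      c(quick = "quick_meal", family = "family_friendly")[[kind]]
    make_hybrid <- function() {
      for (attempt in 1:50) {
        course <- sample(c("lunch", "dinner"), 1)
        excl <- sample(c("nuts", "dairy", "gluten", "shellfish"), 1)
        kind <- sample(c("goal", "taste", "protein"), 1)
        if (kind == "goal") {
          goal <- sample(names(.goal_phrases), 1)
          C <- constraint_set(course = course, health_goals = goal,
                              exclude = excl)
          sig <- Reduce(`|`, lapply(concept_ingredients(goal),
                                    function(t) term_mask(pre, t)))
          q <- sprintf("%s %s without %s", .goal_phrases[[goal]], course,
                       excl)
        } else if (kind == "taste") {
          taste <- sample(names(.taste_map), 1)
          C <- constraint_set(course = course,
                              include = .taste_map[[taste]],
                              exclude = excl)
          sig <- rep(TRUE, length(pre$ids))
          q <- sprintf("healthy %s %s no %s", taste, course, excl)
        } else {
          C <- constraint_set(course = course, exclude = excl,
                              macro = list(protein = list(min = 20)))
          sig <- rep(TRUE, length(pre$ids))
          q <- sprintf("high protein %s %s free", course, excl)
        }
        mask <- satisfies_mask(pre, C, ontology) & sig
        if (sum(mask) >= 1)
          return(list(query = q, category = "hybrid_complex",
                      constraints = C,
                      relevant = pick_relevant(pre, mask)))
      }
      stop("cannot plant a hybrid query on this corpus", call. = FALSE)
    }
    makers <- list(health_goal = make_health, taste_craving = make_taste,
                   occasion_context = make_occasion,
                   hybrid_complex = make_hybrid)
    for (cat in names(counts)) {
      for (i in seq_len(counts[[cat]])) {
        queries[[length(queries) + 1]] <- makers[[cat]]()
      }
    }
  })
  class(queries) <- "benchmark"
  queries
}

#' @export
print.benchmark <- function(x, ...) {
  cats <- table(vapply(unclass(x), `[[`, character(1), "category"))
  cat(sprintf("<benchmark> %d queries (%s)\n", length(x),
              paste(sprintf("%s=%d", names(cats), cats), collapse = ", ")))
  invisible(x)
}

#' Write a benchmark to JSON Lines
#' @param benchmark A `benchmark`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(benchmark, path) {
  lines <- vapply(unclass(benchmark), function(bq) {
    jsonlite::toJSON(list(query = bq$query, category = bq$category,
                          constraints = constraints_to_list(bq$constraints),
                          relevant = bq$relevant),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a benchmark from JSON Lines
#' @param path Path written by [write_benchmark()].
#' @return A `benchmark`.
#' @export
read_benchmark <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    list(query = x$query, category = x$category,
         constraints = constraints_from_list(x$constraints),
         relevant = unlist(x$relevant) %||% character())
  })
  class(out) <- "benchmark"
  out
}
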