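# Core domain types: nutrient vectors, recipes, corpora, constraint sets,
# and JSON Lines corpus I/O.

.nutrient_names <- c("calories", "protein", "fat", "carbohydrates", "fiber")
.courses <- c("breakfast", "lunch", "dinner", "snack", "dessert")

#' Construct a nutrient vector
#'
#' The five-dimensional per-recipe nutrient profile: calories (kcal) and
#' protein, fat, carbohydrates and fiber (grams). All components must be
#' finite and non-negative.
#'
#' @param calories,protein,fat,carbohydrates,fiber Non-negative scalars.
#' @return Named numeric vector of length 5.
#' @export
nutrient_vector <- function(calories, protein, fat, carbohydrates, fiber) {
  n <- c(calories = calories, protein = protein, fat = fat,
         carbohydrates = carbohydrates, fiber = fiber)
  storage.mode(n) <- "double"
  if (any(!is.finite(n))) stop("nutrient values must be finite", call. = FALSE)
  if (any(n < 0)) {
    bad <- names(n)[n < 0][1]
    stop(sprintf("nutrient '%s' is negative", bad), call. = FALSE)
  }
  n
}

#' Construct a recipe
#'
#' A recipe couples structured attributes (normalized ingredient list,
#' course, mass) with a nutrient vector and free text (title, steps).
#' The searchable text is the concatenation of title, ingredients and
#' steps.
#'
#' @param id Unique recipe identifier.
#' @param title Recipe title.
#' @param course One of breakfast, lunch, dinner, snack, dessert.
#' @param ingredients Character vector of ingredient names (normalized at
#'   construction).
#' @param steps Character vector of preparation steps.
#' @param total_mass_g Total dish mass in grams (> 0).
#' @param nutrients A [nutrient_vector()] (or coercible named vector).
#' @return Object of class `recipe`.
#' @export
recipe <- function(id, title, course, ingredients, steps, total_mass_g,
                   nutrients) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("recipe 'id' must be a non-empty string", call. = FALSE)
  if (!course %in% .courses)
    stop(sprintf("unknown course '%s' (expected one of %s)", course,
                 paste(.courses, collapse = ", ")), call. = FALSE)
  ingredients <- normalize_ingredient(as.character(ingredients))
  ingredients <- ingredients[nzchar(ingredients)]
  if (length(ingredients) == 0)
    stop(sprintf("recipe '%s' has an empty ingredient list", id),
         call. = FALSE)
  if (!is.numeric(total_mass_g) || length(total_mass_g) != 1 ||
      !is.finite(total_mass_g) || total_mass_g <= 0)
    stop(sprintf("recipe '%s': total_mass_g must be > 0", id),
         call. = FALSE)
  nutrients <- do.call(nutrient_vector, as.list(nutrients[.nutrient_names]))
  r <- list(id = id, title = as.character(title), course = course,
            ingredients = unique(ingredients),
            steps = as.character(steps),
            total_mass_g = as.numeric(total_mass_g),
            nutrients = nutrients)
  class(r) <- "recipe"
  r
}

#' Searchable text of a recipe
#'
#' Concatenated title, ingredient list and preparation steps; the text
#' stream every retrieval signal (BM25, dense embedding, cross-scorer)
#' operates on.
#'
#' @param r A `recipe`.
#' @return Single string.
#' @export
recipe_text <- function(r) {
  paste(c(r$title, r$ingredients, r$steps), collapse = " ")
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("<recipe %s> %s [%s], %g g\n", x$id, x$title, x$course,
              x$total_mass_g))
  cat("  ingredients:", paste(x$ingredients, collapse = ", "), "\n")
  cat("  nutrients:",
      paste(sprintf("%s=%g", names(x$nutrients), x$nutrients),
            collapse = " "), "\n")
  invisible(x)
}

#' Construct a recipe corpus
#'
#' Ordered collection of recipes with unique ids and O(1) lookup by id.
#'
#' @param recipes List of `recipe` objects.
#' @return Object of class `recipe_corpus`.
#' @export
recipe_corpus <- function(recipes = list()) {
  ids <- vapply(recipes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate recipe id '%s' in corpus", dup), call. = FALSE)
  }
  names(recipes) <- ids
  structure(list(recipes = recipes), class = "recipe_corpus")
}

#' @export
length.recipe_corpus <- function(x) length(x$recipes)

#' @export
print.recipe_corpus <- function(x, ...) {
  cat(sprintf("<recipe_corpus> %d recipes\n", length(x)))
  invisible(x)
}

#' Corpus recipe ids, in corpus order
#' @param corpus A `recipe_corpus`.
#' @return Character vector.
#' @export
corpus_ids <- function(corpus) names(corpus$recipes)

#' Look up a recipe by id
#' @param corpus A `recipe_corpus`.
#' @param id Recipe id.
#' @return The `recipe`; error if absent.
#' @export
get_recipe <- function(corpus, id) {
  r <- corpus$recipes[[id]]
  if (is.null(r)) stop(sprintf("no recipe with id '%s'", id), call. = FALSE)
  r
}

recipe_from_record <- function(rec, line = NA) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  required <- c("id", "title", "course", "ingredients", "steps",
                "total_mass_g", "nutrients")
  missing <- setdiff(required, names(rec))
  if (length(missing) > 0)
    stop(sprintf("missing required field '%s'%s", missing[1], where),
         call. = FALSE)
  nut <- unlist(rec$nutrients)
  miss_n <- setdiff(.nutrient_names, names(nut))
  if (length(miss_n) > 0)
    stop(sprintf("missing nutrient field '%s'%s", miss_n[1], where),
         call. = FALSE)
  extra <- setdiff(names(nut), .nutrient_names)
  if (length(extra) > 0)
    warning(sprintf("ignoring unknown nutrient field(s) %s%s",
                    paste(sQuote(extra), collapse = ", "), where),
            call. = FALSE)
  tryCatch(
    recipe(id = rec$id, title = rec$title, course = rec$course,
           ingredients = unlist(rec$ingredients),
           steps = unlist(rec$steps) %||% character(),
           total_mass_g = rec$total_mass_g,
           nutrients = nut[.nutrient_names]),
    error = function(e) stop(paste0(conditionMessage(e), where),
                             call. = FALSE)
  )
}

#' Read a recipe corpus from JSON Lines
#'
#' One JSON object per line with fields id, title, course, ingredients,
#' steps, total_mass_g and nutrients.{calories,protein,fat,
#' carbohydrates,fiber}. Every record is validated; errors name the
#' offending field and line.
#'
#' @param path Path to a JSONL file.
#' @return A `recipe_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recipes <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("malformed JSON (line %d): %s", i,
                                   conditionMessage(e)), call. = FALSE))
    recipes[[i]] <- recipe_from_record(rec, line = i)
  }
  recipe_corpus(recipes)
}

#' Write a recipe corpus to JSON Lines
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(c, p))`
#' reproduces `c` exactly.
#'
#' @param corpus A `recipe_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus$recipes, function(r) {
    jsonlite::toJSON(
      list(id = r$id, title = r$title, course = r$course,
           ingredients = r$ingredients, steps = r$steps,
           total_mass_g = r$total_mass_g,
           nutrients = as.list(r$nutrients)),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- constraint sets -------------------------------------------------------

#' Construct a structured constraint set
#'
#' The structured object a fuzzy query is refined into: dietary tags,
#' mandatory/forbidden ingredients (or category names), per-meal macro
#' bounds, meal course, and abstract health goals.
#'
#' @param diet_tags Character vector of diet tags (e.g. "vegan").
#' @param include Mandatory ingredient names.
#' @param exclude Forbidden ingredient or category names.
#' @param macro Named list: nutrient -> list(min =, max =) bounds
#'   (kcal for calories, grams otherwise), interpreted per meal.
#' @param course Optional course name.
#' @param health_goals Character vector of health-goal concept names.
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(diet_tags = character(), include = character(),
                           exclude = character(), macro = list(),
                           course = NULL, health_goals = character()) {
  include <- normalize_ingredient(as.character(include))
  exclude <- normalize_ingredient(as.character(exclude))
  if (!is.null(course) && !course %in% .courses)
    stop(sprintf("unknown course '%s'", course), call. = FALSE)
  macro <- lapply(macro, function(b) {
    b <- b[intersect(names(b), c("min", "max"))]
    if (!is.null(b$min) && !is.null(b$max) && b$min > b$max)
      stop("macro bound has min > max", call. = FALSE)
    b
  })
  bad <- setdiff(names(macro), .nutrient_names)
  if (length(bad) > 0)
    stop(sprintf("unknown macro nutrient '%s'", bad[1]), call. = FALSE)
  cs <- list(diet_tags = sort(unique(as.character(diet_tags))),
             include = sort(unique(include[nzchar(include)])),
             exclude = sort(unique(exclude[nzchar(exclude)])),
             macro = macro, course = course,
             health_goals = sort(unique(as.character(health_goals))))
  class(cs) <- "constraint_set"
  cs
}

#' Is a constraint set empty?
#' @param C A `constraint_set`.
#' @return Logical.
#' @export
is_empty_constraints <- function(C) {
  length(C$diet_tags) == 0 && length(C$include) == 0 &&
    length(C$exclude) == 0 && length(C$macro) == 0 &&
    is.null(C$course) && length(C$health_goals) == 0
}

#' Merge two constraint sets
#'
#' Set fields union; conflicting macro bounds intersect, so the tighter
#' bound wins (a 500 kcal ceiling overrides a 600 kcal one). A course
#' already present is kept.
#'
#' @param a,b `constraint_set` objects (or fragments coercible to one).
#' @return Merged `constraint_set`.
#' @export
merge_constraints <- function(a, b) {
  macro <- a$macro
  for (nm in names(b$macro)) {
    bnd <- b$macro[[nm]]
    cur <- macro[[nm]] %||% list()
    if (!is.null(bnd$min)) cur$min <- max(cur$min %||% -Inf, bnd$min)
    if (!is.null(bnd$max)) cur$max <- min(cur$max %||% Inf, bnd$max)
    macro[[nm]] <- cur
  }
  constraint_set(
    diet_tags = c(a$diet_tags, b$diet_tags),
    include = c(a$include, b$include),
    exclude = c(a$exclude, b$exclude),
    macro = macro,
    course = a$course %||% b$course,
    health_goals = c(a$health_goals, b$health_goals))
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set>\n")
  if (length(x$diet_tags)) cat("  diet_tags:", paste(x$diet_tags, collapse = ", "), "\n")
  if (length(x$include)) cat("  include:", paste(x$include, collapse = ", "), "\n")
  if (length(x$exclude)) cat("  exclude:", paste(x$exclude, collapse = ", "), "\n")
  for (nm in names(x$macro)) {
    b <- x$macro[[nm]]
    cat(sprintf("  macro %s: [%s, %s]\n", nm,
                format(b$min %||% -Inf), format(b$max %||% Inf)))
  }
  if (!is.null(x$course)) cat("  course:", x$course, "\n")
  if (length(x$health_goals)) cat("  health_goals:", paste(x$health_goals, collapse = ", "), "\n")
  if (is_empty_constraints(x)) cat("  (empty)\n")
  invisible(x)
}

#' Serialize a constraint set to a JSON-ready list
#' @param C A `constraint_set`.
#' @return Plain list suitable for `jsonlite::toJSON`.
#' @export
constraints_to_list <- function(C) {
  list(diet_tags = C$diet_tags, include = C$include, exclude = C$exclude,
       macro = C$macro, course = C$course, health_goals = C$health_goals)
}

#' Rebuild a constraint set from its serialized list form
#' @param x List as produced by [constraints_to_list()].
#' @return A `constraint_set`.
#' @export
constraints_from_list <- function(x) {
  course <- x$course
  if (!is.character(course) || length(course) != 1 || is.na(course))
    course <- NULL
  constraint_set(diet_tags = unlist(x$diet_tags) %||% character(),
                 include = unlist(x$include) %||% character(),
                 exclude = unlist(x$exclude) %||% character(),
                 macro = lapply(x$macro, as.list),
                 course = course,
                 health_goals = unlist(x$health_goals) %||% character())
}
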