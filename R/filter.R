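# Stage 3: deterministic overlap cross-scorer (pluggable slot for a
# cross-encoder) and hard constraint filtering with category-aware
# exclusion.

# does `term` (ingredient or category member, normalized) match recipe
# ingredient `ing`? exact match, or term appears as a contiguous word
# run inside a compound name ("peanut" matches "peanut butter")
term_matches_ingredient <- function(term, ing) {
  if (term == ing) return(TRUE)
  tw <- strsplit(term, " ", fixed = TRUE)[[1]]
  iw <- strsplit(ing, " ", fixed = TRUE)[[1]]
  n <- length(tw); m <- length(iw)
  if (n >= m) return(FALSE)
  for (s in seq_len(m - n + 1))
    if (identical(iw[s:(s + n - 1)], tw)) return(TRUE)
  FALSE
}

# category lookup tolerant of normalization ("nuts" -> "nut")
category_members <- function(t, ontology) {
  cats <- ontology$categories
  keys <- stats::setNames(names(cats),
                          normalize_ingredient(names(cats)))
  if (t %in% names(cats)) return(cats[[t]])
  if (t %in% names(keys)) return(cats[[keys[[t]]]])
  NULL
}

is_known_term <- function(t, ontology) {
  !is.null(category_members(t, ontology)) ||
    t %in% all_ingredient_names(ontology)
}

expand_exclusion_terms <- function(terms, ontology) {
  out <- character()
  for (t in terms) {
    mem <- category_members(t, ontology)
    # a category term also matches literally; an unknown term is
    # treated as a literal ingredient name
    out <- c(out, t, mem)
  }
  unique(out)
}

match_against_ingredients <- function(terms, ingredients) {
  hits <- list()
  for (t in terms) {
    m <- ingredients[vapply(ingredients, function(ing)
      term_matches_ingredient(t, ing), logical(1))]
    if (length(m) > 0) hits[[t]] <- m
  }
  hits
}

#' Deterministic cross-scorer
#'
#' Default reranking signal standing in the cross-encoder slot:
#' the fraction of distinct query tokens (stopwords dropped, plus any
#' lexicon-expanded intent terms) that occur in the recipe text. Fully
#' deterministic; any function `(q, recipe, expansion) -> [0, 1]` can
#' replace it in the pipeline.
#'
#' @param q Query string.
#' @param r A `recipe`.
#' @param expansion Extra terms (e.g. graph-derived ingredient names for
#'   the query's health goals) added to the query token set.
#' @return Score in \[0, 1\].
#' @export
cross_score <- function(q, r, expansion = character()) {
  qtoks <- unique(normalize_ingredient(
    c(tokenize(q, drop_stopwords = TRUE)[[1]],
      unlist(tokenize(expansion), use.names = FALSE))))
  qtoks <- qtoks[nzchar(qtoks)]
  if (length(qtoks) == 0) return(0)
  dtoks <- unique(normalize_ingredient(tokenize(recipe_text(r))[[1]]))
  length(intersect(qtoks, dtoks)) / length(qtoks)
}

new_verdict <- function(id, violations) {
  structure(list(id = id, passed = length(violations) == 0,
                 violations = violations),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat(sprintf("<filter_verdict %s> %s\n", x$id,
              if (x$passed) "passed" else "FAILED"))
  for (v in x$violations)
    cat(sprintf("  %s: %s\n", v$constraint, v$evidence))
  invisible(x)
}

#' Check one recipe against a constraint set
#'
#' A recipe passes iff (a) no ingredient matches any exclusion, directly
#' or via category expansion, (b) every mandatory ingredient is present,
#' (c) the course matches when constrained, (d) every per-meal macro
#' bound is satisfied by the nutrient vector, and (e) no diet-tag rule
#' is violated. Every violation is recorded with its evidence.
#'
#' @param r A `recipe`.
#' @param C A `constraint_set`.
#' @param ontology Ingredient ontology (categories + diet rules).
#' @return A `filter_verdict`.
#' @export
check_constraints <- function(r, C, ontology = default_ontology(),
                              warn = TRUE) {
  violations <- list()
  # (a) exclusions with category expansion
  for (t in C$exclude) {
    if (warn && !is_known_term(t, ontology))
      warning(sprintf(
        "excluded term '%s' is neither a known category nor ingredient; treated as a literal ingredient name", t),
        call. = FALSE)
    terms <- expand_exclusion_terms(t, ontology)
    hits <- match_against_ingredients(terms, r$ingredients)
    for (h in unlist(hits, use.names = FALSE))
      violations[[length(violations) + 1]] <-
        list(constraint = paste0("exclude:", t), evidence = h)
  }
  # (e) diet-tag rules expand to category exclusions
  for (tag in C$diet_tags) {
    cats <- ontology$diet_rules[[tag]]
    if (is.null(cats)) {
      if (warn)
        warning(sprintf("no diet rule for tag '%s'; tag not enforced", tag),
                call. = FALSE)
      next
    }
    terms <- unique(unlist(ontology$categories[cats], use.names = FALSE))
    hits <- match_against_ingredients(terms, r$ingredients)
    for (h in unlist(hits, use.names = FALSE))
      violations[[length(violations) + 1]] <-
        list(constraint = paste0("diet:", tag), evidence = h)
  }
  # (b) mandatory ingredients
  for (t in C$include) {
    hits <- match_against_ingredients(t, r$ingredients)
    if (length(hits) == 0)
      violations[[length(violations) + 1]] <-
        list(constraint = paste0("include:", t),
             evidence = "ingredient absent")
  }
  # (c) course
  if (!is.null(C$course) && r$course != C$course)
    violations[[length(violations) + 1]] <-
      list(constraint = paste0("course:", C$course),
           evidence = paste0("course is ", r$course))
  # (d) per-meal macro bounds
  for (nm in names(C$macro)) {
    b <- C$macro[[nm]]
    val <- r$nutrients[[nm]]
    if (!is.null(b$min) && val < b$min)
      violations[[length(violations) + 1]] <-
        list(constraint = sprintf("macro:%s>=%g", nm, b$min),
             evidence = sprintf("%s=%g", nm, val))
    if (!is.null(b$max) && val > b$max)
      violations[[length(violations) + 1]] <-
        list(constraint = sprintf("macro:%s<=%g", nm, b$max),
             evidence = sprintf("%s=%g", nm, val))
  }
  new_verdict(r$id, violations)
}

#' Hard-filter candidates against a constraint set
#'
#' Applies [check_constraints()] to every candidate; any recipe
#' violating a negative constraint is discarded. Order-independent and
#' idempotent: survivors keep their input order.
#'
#' @param ids Character vector of candidate recipe ids.
#' @param C A `constraint_set`.
#' @param corpus A `recipe_corpus` resolving the ids.
#' @param ontology Ingredient ontology.
#' @return List with `survivors` (ids, input order) and `verdicts`
#'   (named list of `filter_verdict`, one per candidate).
#' @export
hard_filter <- function(ids, C, corpus, ontology = default_ontology()) {
  # configuration warnings surface once per filter call, not per recipe
  for (t in C$exclude)
    if (!is_known_term(t, ontology))
      warning(sprintf(
        "excluded term '%s' is neither a known category nor ingredient; treated as a literal ingredient name", t),
        call. = FALSE)
  for (tag in C$diet_tags)
    if (is.null(ontology$diet_rules[[tag]]))
      warning(sprintf("no diet rule for tag '%s'; tag not enforced", tag),
              call. = FALSE)
  verdicts <- lapply(ids, function(id)
    check_constraints(get_recipe(corpus, id), C, ontology, warn = FALSE))
  names(verdicts) <- ids
  passed <- vapply(verdicts, `[[`, logical(1), "passed")
  list(survivors = ids[passed], verdicts = verdicts)
}

#' Serialize filter verdicts to a JSON-ready structure
#' @param verdicts List of `filter_verdict` objects.
#' @return Plain list for `jsonlite::toJSON` (the audit trail).
#' @export
verdicts_to_list <- function(verdicts) {
  lapply(verdicts, function(v)
    list(id = v$id, passed = v$passed,
         violations = lapply(v$violations, function(x)
           list(constraint = x$constraint, evidence = x$evidence))))
}
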