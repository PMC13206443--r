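# Stage 1: intent refinement. A deterministic lexicon parser is the
# primary mode; an embedding-centroid nearest-neighbour fallback and a
# pluggable external-parser hook share the same output contract.

match_phrases <- function(q, phrases) {
  qn <- paste0(" ", gsub("[^a-z0-9]+", " ", tolower(q)), " ")
  hits <- vapply(phrases, function(p) {
    pn <- paste0(" ", gsub("[^a-z0-9]+", " ", tolower(p)), " ")
    grepl(pn, qn, fixed = TRUE)
  }, logical(1))
  phrases[hits]
}

# "no nuts" / "without dairy" / "nut free" style negations against known
# categories or ingredient names
extract_exclusions <- function(q, ontology = default_ontology()) {
  qn <- gsub("[^a-z0-9]+", " ", tolower(q))
  known <- unique(c(names(ontology$categories),
                    normalize_ingredient(names(ontology$categories)),
                    all_ingredient_names(ontology)))
  out <- character()
  m <- regmatches(qn, gregexpr("(?:no|without) ([a-z]+)", qn,
                               perl = TRUE))[[1]]
  for (hit in m) {
    w <- normalize_ingredient(sub("^(no|without) ", "", hit))
    if (w %in% known) out <- c(out, w)
  }
  m <- regmatches(qn, gregexpr("([a-z]+)[ -]free", qn))[[1]]
  for (hit in m) {
    w <- normalize_ingredient(sub("[ -]?free$", "", trimws(hit)))
    if (w %in% known) out <- c(out, w)
  }
  unique(out)
}

#' Refine a fuzzy query into a structured constraint set
#'
#' Deterministic rule/lexicon parser: every lexicon phrase found in the
#' query contributes its constraint fragment, negation patterns
#' ("no nuts", "dairy-free") contribute exclusions, and fragments are
#' merged with tighter-bound-wins semantics. An unmatched query yields
#' an empty constraint set, never an error.
#'
#' @param q Query string.
#' @param lexicon Phrase -> fragment mapping, see
#'   [default_intent_lexicon()].
#' @param ontology Ingredient ontology for negation patterns.
#' @return A `constraint_set`.
#' @export
refine_intent <- function(q, lexicon = default_intent_lexicon(),
                          ontology = default_ontology()) {
  C <- constraint_set()
  if (!nzchar(trimws(q))) return(C)
  for (p in match_phrases(q, names(lexicon))) {
    C <- merge_constraints(C, do.call(constraint_set, lexicon[[p]]))
  }
  excl <- extract_exclusions(q, ontology)
  if (length(excl) > 0)
    C <- merge_constraints(C, constraint_set(exclude = excl))
  # a mandatory ingredient that is also excluded cannot be satisfied;
  # the exclusion (safety) wins
  if (length(intersect(C$include, C$exclude)) > 0)
    C$include <- setdiff(C$include, C$exclude)
  C
}

#' Build intent centroids for the semantic fallback
#'
#' Each named intent pairs an embedding centroid (the mean of its
#' defining phrases' embeddings, re-normalized to unit length) with the
#' constraint set the intent stands for.
#'
#' @param intents Named list: intent name -> list(phrases = character,
#'   constraints = `constraint_set`).
#' @param dim Embedding dimension.
#' @return Object of class `intent_centroids`.
#' @export
intent_centroids <- function(intents, dim = 256) {
  stopifnot(length(intents) > 0)
  mat <- t(vapply(intents, function(it) {
    v <- colMeans(embed_text(it$phrases, dim = dim))
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }, numeric(dim)))
  structure(list(matrix = mat,
                 constraints = lapply(intents, `[[`, "constraints"),
                 dim = dim),
            class = "intent_centroids")
}

#' Default intent centroids
#'
#' Centroids for a handful of common dietary intents, used when the
#' rule lexicon fails to match anything and a semantic guess is wanted.
#'
#' @param dim Embedding dimension.
#' @return An `intent_centroids` object.
#' @export
default_intent_centroids <- function(dim = 256) {
  intent_centroids(list(
    light_dinner = list(
      phrases = c("something light for dinner", "light evening meal",
                  "low calorie dinner"),
      constraints = constraint_set(course = "dinner",
                                   macro = list(calories = list(max = 600)))),
    high_protein = list(
      phrases = c("high protein meal", "protein packed lunch",
                  "filling and full of protein"),
      constraints = constraint_set(macro = list(protein = list(min = 20)))),
    immune_support = list(
      phrases = c("immune boosting food", "support my immunity",
                  "meal to fight off a cold"),
      constraints = constraint_set(health_goals = "immune_boosting")),
    vegetarian_meal = list(
      phrases = c("vegetarian meal", "meat free dinner",
                  "veggie lunch idea"),
      constraints = constraint_set(diet_tags = "vegetarian"))
  ), dim = dim)
}

#' Semantic fallback: map a query to the nearest intent centroid
#'
#' Embeds the query and returns the constraint set of the centroid with
#' the highest cosine similarity; ties break by centroid name
#' (lexicographic); similarity below `threshold` yields an empty
#' constraint set.
#'
#' @param q Query string.
#' @param centroids An `intent_centroids` object.
#' @param threshold Minimum cosine similarity to accept a match.
#' @return A `constraint_set`.
#' @export
semantic_fallback <- function(q, centroids = default_intent_centroids(),
                              threshold = 0.3) {
  stopifnot(inherits(centroids, "intent_centroids"))
  qv <- as.numeric(embed_text(q, dim = centroids$dim))
  if (length(qv) != ncol(centroids$matrix))
    stop_config("embedding dimension", "match the centroid dimension")
  sims <- as.numeric(centroids$matrix %*% qv)
  names(sims) <- rownames(centroids$matrix)
  ord <- order(-sims, names(sims))
  best <- ord[1]
  if (sims[best] < threshold) return(constraint_set())
  centroids$constraints[[names(sims)[best]]]
}
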