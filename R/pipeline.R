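# Stage 4 and orchestration: final ranking
# Phi = s_cross + beta * s_graph + gamma * S_nutrition, the rule-based
# critic, and the end-to-end recommendation pipeline in fast and strict
# modes.

#' Ranking / pipeline configuration
#'
#' @param beta Graph-signal weight in the joint and final scores (>= 0).
#' @param gamma Nutrition-score weight in the final score (>= 0).
#' @param pool_size Candidate pool retained before reranking.
#' @param top_k Results returned.
#' @param mode "fast" (no critic) or "strict" (critic verifies top
#'   candidates and removes failures).
#' @param lambda Path-decay base for graph expansion.
#' @param max_hops Maximum graph path length in edges.
#' @param alpha_policy Query class -> alpha table.
#' @return Object of class `ranking_config`.
#' @export
ranking_config <- function(beta = 0.3, gamma = 0.2, pool_size = 200,
                           top_k = 5, mode = c("fast", "strict"),
                           lambda = 0.9, max_hops = 3,
                           alpha_policy = default_alpha_policy()) {
  mode <- match.arg(mode)
  if (beta < 0) stop_config("beta", "be >= 0")
  if (gamma < 0) stop_config("gamma", "be >= 0")
  if (pool_size < top_k) stop_config("pool_size", "be >= top_k")
  if (lambda <= 0 || lambda >= 1) stop_config("lambda", "lie in (0, 1)")
  structure(list(beta = beta, gamma = gamma, pool_size = pool_size,
                 top_k = top_k, mode = mode, lambda = lambda,
                 max_hops = max_hops, alpha_policy = alpha_policy),
            class = "ranking_config")
}

#' Final ranking score
#'
#' `Phi = s_cross + beta * s_graph + gamma * S_nutrition`.
#'
#' @param s_cross,s_graph,s_nutrition Component scores (must be set).
#' @param beta,gamma Weights.
#' @return Phi.
#' @export
final_score <- function(s_cross, s_graph, s_nutrition, beta = 0.3,
                        gamma = 0.2) {
  if (any(is.na(c(s_cross, s_graph, s_nutrition))))
    stop("final_score requires s_cross, s_graph and S_nutrition to be set",
         call. = FALSE)
  s_cross + beta * s_graph + gamma * s_nutrition
}

# beverage cues that contradict a main-meal course request
.beverage_words <- c("smoothie", "shake", "juice", "latte", "cocktail",
                     "lemonade", "milkshake")

#' Rule-based critic verification
#'
#' Re-checks every hard constraint and additionally scans the free-text
#' preparation steps (and title) for excluded-ingredient mentions and
#' for course-incompatible evidence (beverage wording against a
#' lunch/dinner request) that ingredient-level filtering cannot see.
#' Always returns a verdict with a natural-language explanation citing
#' the checked evidence.
#'
#' @param r A `recipe`.
#' @param C A `constraint_set`.
#' @param ontology Ingredient ontology.
#' @return List of class `critic_verdict`: `id`, `passed`,
#'   `explanation`, `violations`.
#' @export
critic_verify <- function(r, C, ontology = default_ontology()) {
  base <- check_constraints(r, C, ontology, warn = FALSE)
  violations <- base$violations
  step_text <- tolower(paste(c(r$title, r$steps), collapse = " "))
  step_toks <- normalize_ingredient(tokenize(step_text)[[1]])
  # hidden excluded ingredients in preparation text
  excl_terms <- unique(c(
    expand_exclusion_terms(C$exclude, ontology),
    unlist(lapply(C$diet_tags, function(tag) {
      cats <- ontology$diet_rules[[tag]]
      unlist(ontology$categories[cats], use.names = FALSE)
    }), use.names = FALSE)))
  for (t in excl_terms) {
    words <- strsplit(t, " ", fixed = TRUE)[[1]]
    n <- length(words)
    hit <- if (n == 1) t %in% step_toks else
      grepl(paste(words, collapse = " "),
            paste(step_toks, collapse = " "), fixed = TRUE)
    if (hit)
      violations[[length(violations) + 1]] <-
        list(constraint = paste0("steps-exclude:", t),
             evidence = sprintf("preparation text mentions '%s'", t))
  }
  # beverage wording against a main-meal course request
  if (!is.null(C$course) && C$course %in% c("lunch", "dinner")) {
    bev <- intersect(.beverage_words, tokenize(step_text)[[1]])
    if (length(bev) > 0)
      violations[[length(violations) + 1]] <-
        list(constraint = paste0("course:", C$course),
             evidence = sprintf("beverage-style dish ('%s')", bev[1]))
  }
  passed <- length(violations) == 0
  explanation <- if (passed) {
    checked <- c(
      if (length(C$exclude) > 0)
        sprintf("verified absence of %s in ingredients and steps",
                paste(C$exclude, collapse = ", ")),
      if (!is.null(C$course))
        sprintf("course '%s' confirmed", r$course),
      sprintf("protein %g g, %g kcal in a %g g serving",
              r$nutrients[["protein"]], r$nutrients[["calories"]],
              r$total_mass_g))
    paste0("PASS: ", paste(checked, collapse = "; "), ".")
  } else {
    det <- vapply(violations, function(v)
      sprintf("%s (%s)", v$constraint, v$evidence), character(1))
    paste0("FAIL: ", paste(det, collapse = "; "), ".")
  }
  structure(list(id = r$id, passed = passed, explanation = explanation,
                 violations = violations),
            class = "critic_verdict")
}

#' @export
print.critic_verdict <- function(x, ...) {
  cat(sprintf("<critic_verdict %s> %s\n", x$id, x$explanation))
  invisible(x)
}

#' End-to-end recommendation
#'
#' Runs the full pipeline in order: intent refinement, adaptive alpha,
#' hybrid retrieval over the whole corpus, knowledge-graph expansion,
#' pool union, cross-scoring, hard constraint filtering, nutrition
#' scoring, final ranking, and (strict mode) critic verification that
#' removes failed candidates and promotes the next-ranked survivors.
#'
#' @param q Query string.
#' @param corpus A `recipe_corpus`.
#' @param graph A `food_graph` (use [empty_food_graph()] to disable).
#' @param sparse,dense Prebuilt indexes over `corpus`.
#' @param config A `ranking_config`.
#' @param lexicon Intent lexicon.
#' @param ontology Ingredient ontology.
#' @param rda Daily RDA table.
#' @param nutrition_cfg A `nutrition_config`.
#' @param concept_lexicon Phrase -> concept mapping for graph expansion.
#' @param constraints Optional pre-parsed `constraint_set` overriding
#'   intent refinement (e.g. oracle ground truth in evaluation).
#' @param cross_fn Cross-scorer `(q, recipe, expansion) -> [0, 1]`;
#'   `NULL` ranks by the normalized hybrid score instead (ablation).
#' @param alpha Fixed alpha overriding the adaptive policy (ablation).
#' @return List of class `recommendation`: `results` (data frame with
#'   per-candidate score breakdown, at most `top_k` rows), `audit`
#'   (stage-by-stage record: constraints, alpha, candidate counts,
#'   verdicts, explanations).
#' @export
recommend <- function(q, corpus, graph, sparse, dense,
                      config = ranking_config(),
                      lexicon = default_intent_lexicon(),
                      ontology = default_ontology(),
                      rda = default_rda(),
                      nutrition_cfg = nutrition_config(),
                      concept_lexicon = default_concept_lexicon(),
                      constraints = NULL, cross_fn = cross_score,
                      alpha = NULL) {
  C <- constraints %||% refine_intent(q, lexicon, ontology)
  a <- alpha %||% compute_alpha(q, config$alpha_policy, lexicon, ontology)
  hybrid <- hybrid_scores(q, sparse, dense, alpha = a)
  concepts <- map_query_to_concepts(q, graph, concept_lexicon,
                                    health_goals = C$health_goals)
  gscores <- graph_expand(graph, concepts, max_len = config$max_hops,
                          lambda = config$lambda)
  gscores <- gscores[names(gscores) %in% corpus_ids(corpus)]
  pool <- source_candidates(hybrid, gscores, beta = config$beta,
                            pool_size = config$pool_size)
  # expansion terms for the cross-scorer: ingredients promoted by the
  # query's concepts (the conceptual bridge made lexical)
  expansion <- if (length(concepts) > 0) {
    ing <- graph_nodes(graph, "ingredient")
    reach <- igraph::ego(graph$igraph, order = config$max_hops,
                         nodes = concepts, mode = "out")
    unique(intersect(unlist(lapply(reach, function(v)
      igraph::V(graph$igraph)$name[as.integer(v)])), ing))
  } else character()
  if (is.null(cross_fn)) {
    pool$s_cross <- pool$s_hybrid
  } else if (identical(cross_fn, cross_score)) {
    # default overlap scorer against the index's precomputed token sets
    qtoks <- unique(normalize_ingredient(
      c(tokenize(q, drop_stopwords = TRUE)[[1]],
        unlist(tokenize(expansion), use.names = FALSE))))
    qtoks <- qtoks[nzchar(qtoks)]
    pool$s_cross <- if (length(qtoks) == 0) 0 else
      vapply(pool$id, function(id)
        length(intersect(qtoks, sparse$norm_tokens[[id]])) /
          length(qtoks), numeric(1))
  } else {
    pool$s_cross <- vapply(pool$id, function(id)
      cross_fn(q, get_recipe(corpus, id), expansion), numeric(1))
  }
  filt <- hard_filter(pool$id, C, corpus, ontology)
  surv <- pool[pool$id %in% filt$survivors, , drop = FALSE]
  breakdowns <- lapply(surv$id, function(id)
    nutrition_breakdown(get_recipe(corpus, id), rda, nutrition_cfg))
  surv$s_nutrition <- vapply(breakdowns, `[[`, numeric(1), "s_nutrition")
  surv$phi <- final_score(surv$s_cross, surv$s_graph, surv$s_nutrition,
                          beta = config$beta, gamma = config$gamma)
  surv <- surv[order(-surv$phi, surv$id), , drop = FALSE]
  rownames(surv) <- NULL
  critic_verdicts <- list()
  if (config$mode == "strict" && nrow(surv) > 0) {
    keep <- logical(nrow(surv))
    verified <- 0
    for (i in seq_len(nrow(surv))) {
      if (verified >= config$top_k) break
      v <- critic_verify(get_recipe(corpus, surv$id[i]), C, ontology)
      critic_verdicts[[surv$id[i]]] <- v
      if (v$passed) {
        keep[i] <- TRUE
        verified <- verified + 1
      }
    }
    surv <- surv[keep, , drop = FALSE]
    rownames(surv) <- NULL
  }
  results <- utils::head(surv, config$top_k)
  results$title <- vapply(results$id, function(id)
    get_recipe(corpus, id)$title, character(1))
  audit <- list(
    query = q, mode = config$mode,
    constraints = constraints_to_list(C), alpha = a,
    concepts = concepts,
    n_corpus = length(corpus), n_pool = nrow(pool),
    n_after_filter = length(filt$survivors),
    n_returned = nrow(results),
    filter_verdicts = verdicts_to_list(filt$verdicts),
    critic_verdicts = lapply(critic_verdicts, function(v)
      list(id = v$id, passed = v$passed, explanation = v$explanation)),
    binding_constraints = if (nrow(results) == 0)
      constraints_to_list(C) else NULL)
  structure(list(results = results, audit = audit),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("<recommendation> query: \"%s\" (%s mode, alpha=%.2f)\n",
              x$audit$query, x$audit$mode, x$audit$alpha))
  if (nrow(x$results) == 0) {
    cat("  no recipe satisfies the constraints\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$results))) {
    r <- x$results[i, ]
    cat(sprintf("  %d. %s (%s)  Phi=%.3f  cross=%.2f graph=%.2f nutr=%.2f\n",
                i, r$title, r$id, r$phi, r$s_cross, r$s_graph,
                r$s_nutrition))
  }
  invisible(x)
}

#' Write a recommendation audit record as JSON
#' @param rec A `recommendation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(rec, path) {
  out <- list(audit = rec$audit,
              results = rec$results)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
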