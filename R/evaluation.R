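# Ranking metrics (Recall@k, semantic recall, NDCG@k, constraint
# satisfaction rate) and the component-ablation harness.

#' Recall at k
#'
#' `|top-k intersect relevant| / |relevant|`. Undefined (NA) for an
#' empty relevant set; callers exclude NA from averages.
#'
#' @param ranked Character vector of ranked recipe ids.
#' @param relevant Character vector of relevant ids.
#' @param k Cutoff (>= 1).
#' @return Value in \[0, 1\], or NA.
#' @export
recall_at_k <- function(ranked, relevant, k = 5) {
  stopifnot(k >= 1)
  if (length(relevant) == 0) return(NA_real_)
  length(intersect(utils::head(ranked, k), relevant)) / length(relevant)
}

#' Semantic recall at k (hit rate)
#'
#' 1 if the top-k contains at least one relevant id, else 0; its mean
#' over queries is the fraction of queries answered with at least one
#' relevant recommendation.
#'
#' @inheritParams recall_at_k
#' @return 0, 1, or NA for an empty relevant set.
#' @export
semantic_recall_at_k <- function(ranked, relevant, k = 5) {
  stopifnot(k >= 1)
  if (length(relevant) == 0) return(NA_real_)
  as.numeric(length(intersect(utils::head(ranked, k), relevant)) > 0)
}

#' Normalized discounted cumulative gain at k
#'
#' DCG with `log2(rank + 1)` discount over the top-k, normalized by the
#' ideal DCG of the grade multiset; 0 by convention when all grades are
#' zero.
#'
#' @param ranked Character vector of ranked ids.
#' @param grades Named non-negative numeric vector (id -> relevance
#'   grade); ids absent from `grades` count as grade 0.
#' @param k Cutoff.
#' @return Value in \[0, 1\].
#' @export
ndcg_at_k <- function(ranked, grades, k = 5) {
  stopifnot(k >= 1, all(grades >= 0))
  top <- utils::head(ranked, k)
  g <- unname(ifelse(top %in% names(grades), grades[top], 0))
  dcg <- sum(g / log2(seq_along(g) + 1))
  ideal <- sort(as.numeric(grades), decreasing = TRUE)
  ideal <- utils::head(ideal, k)
  idcg <- sum(ideal / log2(seq_along(ideal) + 1))
  if (idcg <= 0) return(0)
  dcg / idcg
}

#' Constraint satisfaction rate (percent)
#'
#' Micro-averaged share of recommended top-k items that satisfy all
#' ground-truth hard constraints (checked against the ground truth, not
#' against whatever constraints the system parsed). A query with an
#' empty result list contributes 0 satisfied out of k slots.
#'
#' @param results List of character vectors (ranked ids per query).
#' @param constraints List of ground-truth `constraint_set`s (same
#'   length).
#' @param corpus A `recipe_corpus`.
#' @param ontology Ingredient ontology.
#' @param k Cutoff, default 5.
#' @return Percent in \[0, 100\].
#' @export
cs_rate <- function(results, constraints, corpus,
                    ontology = default_ontology(), k = 5) {
  stopifnot(length(results) == length(constraints))
  sat <- 0; total <- 0
  for (i in seq_along(results)) {
    top <- utils::head(results[[i]], k)
    if (length(top) == 0) {
      total <- total + k
      next
    }
    ok <- vapply(top, function(id)
      check_constraints(get_recipe(corpus, id), constraints[[i]],
                        ontology, warn = FALSE)$passed, logical(1))
    sat <- sat + sum(ok)
    total <- total + length(top)
  }
  if (total == 0) return(100)
  100 * sat / total
}

#' Evaluate the pipeline on a benchmark
#'
#' Runs [recommend()] for every benchmark query and aggregates
#' Recall@k, SR@k, NDCG@k (binary grades from the planted relevance)
#' and CS-Rate against the ground-truth constraints.
#'
#' @param benchmark A `benchmark`.
#' @param corpus,graph,sparse,dense Pipeline artifacts.
#' @param config A `ranking_config`.
#' @param k Metric cutoff, default `config$top_k`.
#' @param variant One of "full", "no_graph", "fixed_alpha",
#'   "no_cross_encoder" (component ablations).
#' @param fixed_alpha Alpha used by the fixed_alpha variant.
#' @param ... Passed on to [recommend()].
#' @return List of class `eval_report`: per-metric means, per-query
#'   values, and the configuration fingerprint.
#' @export
evaluate_benchmark <- function(benchmark, corpus, graph, sparse, dense,
                               config = ranking_config(),
                               k = config$top_k,
                               variant = c("full", "no_graph",
                                           "fixed_alpha",
                                           "no_cross_encoder"),
                               fixed_alpha = 0.7, ...) {
  variant <- match.arg(variant)
  cfg <- config
  alpha <- NULL
  cross_fn <- cross_score
  g <- graph
  if (variant == "no_graph") {
    cfg$beta <- 0
    g <- empty_food_graph()
  } else if (variant == "fixed_alpha") {
    alpha <- fixed_alpha
  } else if (variant == "no_cross_encoder") {
    cross_fn <- NULL
  }
  n <- length(benchmark)
  per_query <- data.frame(query = character(n), category = character(n),
                          recall = numeric(n), sr = numeric(n),
                          ndcg = numeric(n), alpha = numeric(n),
                          stringsAsFactors = FALSE)
  results <- vector("list", n)
  gts <- vector("list", n)
  for (i in seq_len(n)) {
    bq <- benchmark[[i]]
    rec <- recommend(bq$query, corpus, g, sparse, dense, config = cfg,
                     cross_fn = cross_fn, alpha = alpha, ...)
    ids <- rec$results$id
    grades <- stats::setNames(rep(1, length(bq$relevant)), bq$relevant)
    per_query$query[i] <- bq$query
    per_query$category[i] <- bq$category
    per_query$recall[i] <- recall_at_k(ids, bq$relevant, k)
    per_query$sr[i] <- semantic_recall_at_k(ids, bq$relevant, k)
    per_query$ndcg[i] <- ndcg_at_k(ids, grades, k)
    per_query$alpha[i] <- rec$audit$alpha
    results[[i]] <- ids
    gts[[i]] <- bq$constraints
  }
  csr <- cs_rate(results, gts, corpus, k = k)
  structure(list(
    variant = variant, k = k, n_queries = n,
    recall = mean(per_query$recall, na.rm = TRUE),
    sr = mean(per_query$sr, na.rm = TRUE),
    ndcg = mean(per_query$ndcg, na.rm = TRUE),
    cs_rate = csr,
    per_query = per_query, results = results,
    fingerprint = list(beta = cfg$beta, gamma = cfg$gamma,
                       pool_size = cfg$pool_size, top_k = cfg$top_k,
                       mode = cfg$mode, variant = variant,
                       fixed_alpha = if (variant == "fixed_alpha")
                         fixed_alpha else NULL)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report %s> %d queries: R@%d=%.3f SR@%d=%.3f NDCG@%d=%.3f CS-Rate=%.1f%%\n",
    x$variant, x$n_queries, x$k, x$recall, x$k, x$sr, x$k, x$ndcg,
    x$cs_rate))
  invisible(x)
}

#' Component ablation harness
#'
#' Evaluates the same benchmark under each requested variant: the full
#' pipeline, graph expansion removed, the adaptive alpha replaced by a
#' fixed 0.7, or the cross-scorer replaced by the hybrid score.
#'
#' @inheritParams evaluate_benchmark
#' @param variants Subset of the four variant names.
#' @return Named list of `eval_report`s.
#' @export
run_ablation <- function(benchmark, corpus, graph, sparse, dense,
                         config = ranking_config(),
                         variants = c("full", "no_graph", "fixed_alpha",
                                      "no_cross_encoder"),
                         fixed_alpha = 0.7, ...) {
  known <- c("full", "no_graph", "fixed_alpha", "no_cross_encoder")
  bad <- setdiff(variants, known)
  if (length(bad) > 0)
    stop_config("variants", sprintf("be among %s (got '%s')",
                                    paste(known, collapse = ", "),
                                    bad[1]))
  out <- lapply(variants, function(v)
    evaluate_benchmark(benchmark, corpus, graph, sparse, dense,
                       config = config, variant = v,
                       fixed_alpha = fixed_alpha, ...))
  names(out) <- variants
  out
}
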