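# Stage 2a: sparse (Okapi BM25) and dense retrieval indexes, the
# rule-based query classifier behind the adaptive mixing weight alpha,
# and hybrid scoring s_hybrid = alpha * s_dense + (1 - alpha) * s_bm25.

#' Build an Okapi BM25 sparse index
#'
#' Indexes the concatenated recipe text (title + ingredients + steps)
#' with conventional Okapi parameters. The idf uses the non-negative
#' form `log(1 + (N - df + 0.5) / (df + 0.5))` so scores are always
#' >= 0 and exactly 0 when no query term occurs in a document.
#'
#' @param corpus A `recipe_corpus`.
#' @param k1 Term-frequency saturation (> 0), default 1.5.
#' @param b Length-normalization strength in \[0, 1\], default 0.75.
#' @return Object of class `sparse_index`.
#' @export
build_sparse_index <- function(corpus, k1 = 1.5, b = 0.75) {
  if (k1 <= 0) stop_config("k1", "be > 0")
  if (b < 0 || b > 1) stop_config("b", "lie in [0, 1]")
  ids <- corpus_ids(corpus)
  doc_tokens <- lapply(corpus$recipes, function(r)
    tokenize(recipe_text(r))[[1]])
  doc_tf <- lapply(doc_tokens, function(toks) {
    tab <- table(toks)
    stats::setNames(as.numeric(tab), names(tab))
  })
  names(doc_tf) <- ids
  doc_len <- vapply(doc_tf, sum, numeric(1))
  # inverted postings: term -> (doc position -> tf), for vectorized scoring
  all_terms <- unlist(lapply(doc_tf, names), use.names = FALSE)
  all_tf <- unlist(doc_tf, use.names = FALSE)
  all_doc <- rep(seq_along(ids),
                 times = vapply(doc_tf, length, integer(1)))
  postings <- split(data.frame(doc = all_doc, tf = all_tf), all_terms)
  df <- vapply(postings, nrow, integer(1))
  # normalized (singularized) token sets per doc feed the overlap
  # cross-scorer without re-tokenizing at query time
  vocab <- unique(all_terms)
  norm_map <- stats::setNames(normalize_ingredient(vocab), vocab)
  norm_tokens <- lapply(doc_tf, function(tf)
    unique(unname(norm_map[names(tf)])))
  structure(list(ids = ids, doc_tf = doc_tf,
                 doc_len = stats::setNames(as.numeric(doc_len), ids),
                 avgdl = if (length(ids)) mean(doc_len) else 0,
                 df = stats::setNames(as.numeric(df), names(df)),
                 postings = postings, norm_tokens = norm_tokens,
                 n_docs = length(ids), k1 = k1, b = b),
            class = "sparse_index")
}

#' BM25 scores of a query against all indexed documents
#'
#' @param index A `sparse_index`.
#' @param q Query string.
#' @return Named numeric vector (recipe id -> s_bm25), corpus order.
#' @export
bm25_scores <- function(index, q) {
  scores <- stats::setNames(numeric(index$n_docs), index$ids)
  terms <- unique(tokenize(q)[[1]])
  terms <- terms[terms %in% names(index$df)]
  if (length(terms) == 0 || index$n_docs == 0) return(scores)
  k1 <- index$k1; b <- index$b; N <- index$n_docs
  len_norm <- k1 * (1 - b + b * unname(index$doc_len) / index$avgdl)
  for (t in terms) {
    idf <- log(1 + (N - index$df[[t]] + 0.5) / (index$df[[t]] + 0.5))
    p <- index$postings[[t]]
    scores[p$doc] <- scores[p$doc] +
      idf * p$tf * (k1 + 1) / (p$tf + len_norm[p$doc])
  }
  scores
}

#' BM25 score of a query against one indexed recipe
#'
#' @param index A `sparse_index`.
#' @param q Query string.
#' @param id Recipe id (must be indexed).
#' @return Non-negative scalar.
#' @export
bm25_score <- function(index, q, id) {
  if (!id %in% index$ids)
    stop(sprintf("recipe '%s' is not indexed", id), call. = FALSE)
  bm25_scores(index, q)[[id]]
}

#' Build a dense embedding index
#'
#' Embeds every recipe's text with the deterministic hashed embedder
#' (or any drop-in `embed_fn` with the same contract) and stores the
#' unit-norm vectors.
#'
#' @param corpus A `recipe_corpus`.
#' @param dim Embedding dimension.
#' @param embed_fn Function(texts, dim) -> matrix of unit-norm rows.
#' @return Object of class `dense_index`.
#' @export
build_dense_index <- function(corpus, dim = 256, embed_fn = embed_text) {
  ids <- corpus_ids(corpus)
  texts <- vapply(corpus$recipes, recipe_text, character(1))
  mat <- embed_fn(texts, dim = dim)
  rownames(mat) <- ids
  structure(list(matrix = mat, dim = dim, embed_fn = embed_fn),
            class = "dense_index")
}

#' Cosine similarities of a query against all indexed recipes
#'
#' @param index A `dense_index`.
#' @param q Query string.
#' @return Named numeric vector (recipe id -> s_dense), corpus order.
#' @export
dense_scores <- function(index, q) {
  qv <- as.numeric(index$embed_fn(q, dim = index$dim))
  if (length(qv) != index$dim)
    stop_config("embedding dimension", "match the index dimension")
  if (nrow(index$matrix) == 0)
    return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(index$matrix %*% qv), rownames(index$matrix))
}

#' Cosine similarity of a query and one recipe
#' @param index A `dense_index`.
#' @param q Query string.
#' @param id Recipe id.
#' @return Scalar in \[-1, 1\].
#' @export
dense_score <- function(index, q, id) {
  if (!id %in% rownames(index$matrix))
    stop(sprintf("recipe '%s' is not indexed", id), call. = FALSE)
  dense_scores(index, q)[[id]]
}

#' Default adaptive-weighting policy
#'
#' Query class -> alpha, the dense-score weight in hybrid retrieval:
#' ingredient lists lean lexical (0.35), short dish names strongly
#' lexical (0.20), intent-rich queries lean semantic (0.65), everything
#' else balanced (0.50).
#'
#' @return Named numeric vector over the four query classes.
#' @export
default_alpha_policy <- function() {
  c(ingredient_list = 0.35, dish_name = 0.20, intent_marker = 0.65,
    default = 0.50)
}

is_food_token <- function(x, ontology = default_ontology()) {
  normalize_ingredient(x) %in% all_ingredient_names(ontology)
}

#' Classify a query's structure
#'
#' Priority-ordered rules: (1) `ingredient_list` if the query splits on
#' commas into two or more known food names; (2) `intent_marker` if any
#' intent-lexicon phrase or abstract goal word occurs; (3) `dish_name`
#' if the query has at most two tokens, all known dish or food words;
#' (4) `default` otherwise.
#'
#' @param q Query string.
#' @param lexicon Intent lexicon (phrases count as intent markers).
#' @param ontology Ingredient ontology (food-token recognition).
#' @return One of "ingredient_list", "dish_name", "intent_marker",
#'   "default".
#' @export
classify_query <- function(q, lexicon = default_intent_lexicon(),
                           ontology = default_ontology()) {
  segs <- trimws(strsplit(q, ",", fixed = TRUE)[[1]])
  segs <- segs[nzchar(segs)]
  if (length(segs) >= 2 && all(is_food_token(segs, ontology)))
    return("ingredient_list")
  markers <- unique(c(names(lexicon), .intent_markers,
                      names(default_concept_lexicon())))
  if (length(match_phrases(q, markers)) > 0)
    return("intent_marker")
  toks <- tokenize(q)[[1]]
  dishish <- c(.dish_names, all_ingredient_names(ontology))
  if (length(toks) >= 1 && length(toks) <= 2 &&
      all(normalize_ingredient(toks) %in%
            unlist(strsplit(dishish, " "), use.names = FALSE) |
          normalize_ingredient(toks) %in% dishish))
    return("dish_name")
  "default"
}

#' Compute the adaptive hybrid mixing weight
#'
#' @param q Query string.
#' @param policy Query class -> alpha table.
#' @param lexicon,ontology Passed to [classify_query()].
#' @return Alpha in \[0, 1\].
#' @export
compute_alpha <- function(q, policy = default_alpha_policy(),
                          lexicon = default_intent_lexicon(),
                          ontology = default_ontology()) {
  if (any(policy < 0 | policy > 1)) stop_config("alpha", "lie in [0, 1]")
  unname(policy[[classify_query(q, lexicon, ontology)]])
}

#' Score the whole corpus with the hybrid signal
#'
#' Computes BM25 and dense scores for every indexed recipe, min-max
#' normalizes each signal to \[0, 1\] over the candidate pool, and mixes
#' them: `s_hybrid = alpha * s_dense + (1 - alpha) * s_bm25`.
#'
#' @param q Query string.
#' @param sparse A `sparse_index`.
#' @param dense A `dense_index`.
#' @param alpha Mixing weight (computed from the policy if `NULL`).
#' @param policy Alpha policy used when `alpha` is `NULL`.
#' @return Data frame (id, s_bm25, s_dense, s_hybrid), corpus order,
#'   with raw scores in `s_bm25_raw` / `s_dense_raw` attributes-free
#'   columns `s_bm25` and `s_dense` already normalized.
#' @export
hybrid_scores <- function(q, sparse, dense, alpha = NULL,
                          policy = default_alpha_policy()) {
  alpha <- alpha %||% compute_alpha(q, policy)
  sb <- bm25_scores(sparse, q)
  sd <- dense_scores(dense, q)
  stopifnot(identical(names(sb), names(sd)))
  nb <- minmax_normalize(sb)
  nd <- minmax_normalize(sd)
  data.frame(id = names(sb), s_bm25 = as.numeric(nb),
             s_dense = as.numeric(nd),
             s_hybrid = alpha * as.numeric(nd) + (1 - alpha) * as.numeric(nb),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hybrid top-k retrieval
#'
#' Ranks the corpus by the normalized hybrid score, descending, with
#' ties broken by ascending recipe id, and returns the top `k` rows.
#'
#' @inheritParams hybrid_scores
#' @param k Number of candidates to return (>= 1).
#' @return Data frame of at most `min(k, corpus size)` rows.
#' @export
hybrid_retrieve <- function(q, sparse, dense, k,
                            alpha = NULL, policy = default_alpha_policy()) {
  stopifnot(k >= 1)
  df <- hybrid_scores(q, sparse, dense, alpha = alpha, policy = policy)
  if (nrow(df) == 0) return(df)
  df <- df[order(-df$s_hybrid, df$id), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}
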