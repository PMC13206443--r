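# Deterministic text embedder: L2-normalized hashed bag of tokens and
# character trigrams. Fixed dimension and hash seed make embeddings fully
# reproducible with no model weights; any encoder honouring the same
# contract (fixed-dim unit vectors, cosine comparable) can be plugged in
# through the `embed_fn` arguments of the dense index builders.

char_trigrams <- function(tok) {
  padded <- paste0("#", tok, "#")
  n <- nchar(padded)
  if (n < 3) return(character())
  substring(padded, 1:(n - 2), 3:n)
}

text_features <- function(text) {
  toks <- tokenize(text)[[1]]
  c(toks, unlist(lapply(toks, char_trigrams), use.names = FALSE))
}

#' Embed texts as hashed bag-of-feature vectors
#'
#' Features are word tokens plus boundary-padded character trigrams;
#' each feature is hashed (fixed seed) into one of `dim` buckets and
#' counted; the count vector is L2-normalized. Cosine similarity between
#' such vectors is the dense relevance signal.
#'
#' @param texts Character vector.
#' @param dim Embedding dimension (default 256).
#' @param seed Hash seed (fixed; changing it changes the feature space).
#' @return Numeric matrix, one unit-norm row per text.
#' @export
embed_text <- function(texts, dim = 256, seed = 7L) {
  stopifnot(dim >= 2)
  mat <- matrix(0, nrow = length(texts), ncol = dim)
  for (i in seq_along(texts)) {
    feats <- text_features(texts[i])
    if (length(feats) == 0) next
    tab <- table(feats)
    idx <- vapply(names(tab), hash_string, numeric(1), seed = seed) %% dim + 1
    v <- numeric(dim)
    for (j in seq_along(idx)) v[idx[j]] <- v[idx[j]] + tab[[j]]
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    mat[i, ] <- v
  }
  rownames(mat) <- names(texts)
  mat
}
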