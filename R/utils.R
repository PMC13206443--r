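#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# words that carry no retrieval signal in short dietary queries
.stopwords <- c(
  "a", "an", "and", "the", "for", "with", "without", "no", "not", "of",
  "to", "in", "on", "or", "but", "something", "some", "me", "my", "i",
  "want", "please", "meal", "meals", "recipe", "recipes"
)

#' Tokenize free text
#'
#' Lowercases and splits on any non-alphanumeric run. Used consistently by
#' the sparse index, the hashed embedder and the overlap cross-scorer so
#' that all retrieval signals see the same token stream.
#'
#' @param x Character vector of texts.
#' @param drop_stopwords Drop common function words.
#' @return List of character vectors (one per input text).
#' @export
tokenize <- function(x, drop_stopwords = FALSE) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (drop_stopwords) toks <- lapply(toks, setdiff, y = .stopwords)
  toks
}

# irregulars / mass nouns that must not be stripped of a trailing "s"
.plural_keep <- c(
  "couscous", "hummus", "asparagus", "molasses", "swiss", "citrus"
)

singularize_word <- function(w) {
  keep <- w %in% .plural_keep | nchar(w) <= 3 | grepl("ss$", w)
  out <- w
  ies <- !keep & grepl("ies$", w)
  out[ies] <- sub("ies$", "y", w[ies])
  es <- !keep & !ies & grepl("(oes|ches|shes|xes)$", w)
  out[es] <- sub("es$", "", w[es])
  s <- !keep & !ies & !es & grepl("s$", w)
  out[s] <- sub("s$", "", w[s])
  out
}

#' Normalize an ingredient name
#'
#' Lowercase, trim, collapse internal whitespace and singularize each word,
#' so that exclusion matching ("peanuts" vs "peanut") is deterministic.
#'
#' @param x Character vector of ingredient or category names.
#' @return Character vector of normalized names.
#' @export
normalize_ingredient <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[_]+", " ", x)
  x <- gsub("\\s+", " ", x)
  vapply(strsplit(x, " ", fixed = TRUE), function(ws) {
    paste(singularize_word(ws), collapse = " ")
  }, character(1))
}

# deterministic polynomial string hash (31-base, fixed seed), used by the
# hashed bag-of-features embedder
hash_string <- function(s, seed = 7L, mod = 16777213) {
  h <- as.numeric(seed)
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% mod
  h
}

minmax_normalize <- function(x) {
  if (length(x) == 0) return(x)
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

stop_config <- function(key, constraint) {
  stop(sprintf("invalid configuration: '%s' must %s", key, constraint),
       call. = FALSE)
}
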