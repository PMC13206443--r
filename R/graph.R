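# Stage 2b: the typed food knowledge graph and path-decay expansion
# scoring s_graph(q, r) = sum over simple paths p of lambda^length(p).

.edge_types <- c("promotes", "has_ingredient", "contains_ingredient")
.node_types <- c("concept", "ingredient", "recipe")

check_edge_types <- function(nodes, edges) {
  type_of <- stats::setNames(nodes$type, nodes$name)
  for (i in seq_len(nrow(edges))) {
    et <- edges$type[i]
    st <- type_of[[edges$from[i]]]
    tt <- type_of[[edges$to[i]]]
    ok <- switch(et,
      promotes = st == "concept" && tt %in% c("concept", "ingredient"),
      has_ingredient = st == "concept" && tt == "ingredient",
      contains_ingredient = st == "ingredient" && tt == "recipe",
      FALSE)
    if (!ok)
      stop(sprintf("edge %s -[%s]-> %s violates type constraints (%s -> %s)",
                   edges$from[i], et, edges$to[i], st, tt), call. = FALSE)
    if (edges$from[i] == edges$to[i])
      stop(sprintf("self-loop on node '%s'", edges$from[i]), call. = FALSE)
  }
}

#' Construct a food knowledge graph
#'
#' Directed typed graph over concept, ingredient and recipe nodes with
#' edge types promotes (concept -> concept | ingredient), has_ingredient
#' (concept -> ingredient) and contains_ingredient (ingredient ->
#' recipe). Type constraints are validated at construction.
#'
#' @param nodes Data frame with columns `name`, `type`.
#' @param edges Data frame with columns `from`, `type`, `to`.
#' @return Object of class `food_graph` (wraps an igraph).
#' @export
food_graph <- function(nodes, edges) {
  stopifnot(all(c("name", "type") %in% names(nodes)),
            all(c("from", "type", "to") %in% names(edges)))
  nodes$name <- as.character(nodes$name)
  if (anyDuplicated(nodes$name))
    stop("duplicate node names in graph", call. = FALSE)
  if (!all(nodes$type %in% .node_types))
    stop("unknown node type in graph", call. = FALSE)
  if (nrow(edges) > 0) {
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes$name)
    if (length(missing) > 0)
      stop(sprintf("edge references unknown node '%s'", missing[1]),
           call. = FALSE)
    check_edge_types(nodes, edges)
  }
  ig <- igraph::graph_from_data_frame(
    d = edges[, c("from", "to", "type"), drop = FALSE],
    directed = TRUE, vertices = nodes)
  structure(list(igraph = ig), class = "food_graph")
}

#' Empty food graph
#' @return A `food_graph` with no nodes.
#' @export
empty_food_graph <- function() {
  food_graph(data.frame(name = character(), type = character()),
             data.frame(from = character(), type = character(),
                        to = character()))
}

graph_nodes <- function(g, type = NULL) {
  nm <- igraph::V(g$igraph)$name
  if (is.null(type)) return(nm)
  nm[igraph::V(g$igraph)$type == type]
}

#' @export
print.food_graph <- function(x, ...) {
  tys <- igraph::V(x$igraph)$type
  cat(sprintf("<food_graph> %d concepts, %d ingredients, %d recipes, %d edges\n",
              sum(tys == "concept"), sum(tys == "ingredient"),
              sum(tys == "recipe"), igraph::ecount(x$igraph)))
  invisible(x)
}

#' Write a food graph as a TSV edge list
#'
#' Node types are declared in a `#node` header block, one line per node
#' (`#node<TAB>name<TAB>type`), followed by tab-separated edge rows
#' (source, edge_type, target).
#'
#' @param g A `food_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_food_graph <- function(g, path) {
  nodes <- sprintf("#node\t%s\t%s", igraph::V(g$igraph)$name,
                   igraph::V(g$igraph)$type)
  ed <- igraph::as_data_frame(g$igraph, what = "edges")
  rows <- if (nrow(ed) > 0) sprintf("%s\t%s\t%s", ed$from, ed$type, ed$to)
          else character()
  writeLines(c(nodes, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a food graph from a TSV edge list
#' @param path Path written by [write_food_graph()].
#' @return A `food_graph`.
#' @export
read_food_graph <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_node <- vapply(parts, function(p) p[1] == "#node", logical(1))
  nodes <- do.call(rbind, lapply(parts[is_node], function(p)
    data.frame(name = p[2], type = p[3], stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(parts[!is_node], function(p)
    data.frame(from = p[1], type = p[2], to = p[3],
               stringsAsFactors = FALSE)))
  food_graph(nodes %||% data.frame(name = character(), type = character()),
             edges %||% data.frame(from = character(), type = character(),
                                   to = character()))
}

#' Map a query to graph concept nodes
#'
#' Scans the query (and, optionally, refined health-goal names) for
#' concept-lexicon phrases and returns the matching concept nodes
#' present in the graph.
#'
#' @param q Query string.
#' @param graph A `food_graph`.
#' @param concept_lexicon Phrase -> concept mapping.
#' @param health_goals Extra goal names (from a refined constraint set)
#'   to map alongside the raw query text.
#' @return Character vector of concept node names (possibly empty).
#' @export
map_query_to_concepts <- function(q, graph,
                                  concept_lexicon = default_concept_lexicon(),
                                  health_goals = character()) {
  text <- paste(c(q, gsub("_", " ", health_goals)), collapse = " ; ")
  hits <- match_phrases(text, names(concept_lexicon))
  concepts <- unique(unname(concept_lexicon[hits]))
  # goal names that are themselves concept node names map directly
  concepts <- unique(c(concepts, health_goals))
  intersect(concepts, graph_nodes(graph, "concept"))
}

#' Enumerate decayed paths between two nodes
#'
#' All simple directed paths from `source` to `target` with at most
#' `max_len` edges; each path carries weight `lambda^length`.
#'
#' @param graph A `food_graph`.
#' @param source,target Node names.
#' @param max_len Maximum path length in edges (>= 1).
#' @param lambda Decay base in (0, 1), default 0.9.
#' @return List of `list(nodes, length, weight)`, one per path.
#' @export
enumerate_paths <- function(graph, source, target, max_len = 3,
                            lambda = 0.9) {
  stopifnot(max_len >= 1)
  if (lambda <= 0 || lambda >= 1) stop_config("lambda", "lie in (0, 1)")
  nm <- graph_nodes(graph)
  if (!source %in% nm) stop(sprintf("unknown node '%s'", source), call. = FALSE)
  if (!target %in% nm) stop(sprintf("unknown node '%s'", target), call. = FALSE)
  paths <- igraph::all_simple_paths(graph$igraph, from = source,
                                    to = target, mode = "out",
                                    cutoff = max_len)
  lapply(paths, function(p) {
    len <- length(p) - 1
    list(nodes = igraph::V(graph$igraph)$name[as.integer(p)],
         length = len, weight = lambda^len)
  })
}

#' Graph-expansion score of one recipe
#'
#' Sum of decayed path weights over all simple paths from every query
#' concept to the recipe node; 0 when the recipe is unreachable.
#'
#' @param graph A `food_graph`.
#' @param concepts Character vector of concept node names (V_q).
#' @param id Recipe node name.
#' @param max_len Maximum path length in edges.
#' @param lambda Decay base.
#' @return Non-negative scalar.
#' @export
graph_score <- function(graph, concepts, id, max_len = 3, lambda = 0.9) {
  if (length(concepts) == 0 || !id %in% graph_nodes(graph)) return(0)
  sum(vapply(concepts, function(cpt) {
    if (!cpt %in% graph_nodes(graph)) return(0)
    sum(vapply(enumerate_paths(graph, cpt, id, max_len, lambda),
               `[[`, numeric(1), "weight"))
  }, numeric(1)))
}

#' Graph-expansion scores for every reachable recipe
#'
#' @inheritParams graph_score
#' @return Named numeric vector (recipe node -> s_graph) over recipes
#'   reachable from any concept in `concepts`; empty when none.
#' @export
graph_expand <- function(graph, concepts, max_len = 3, lambda = 0.9) {
  if (lambda <= 0 || lambda >= 1) stop_config("lambda", "lie in (0, 1)")
  recipes <- graph_nodes(graph, "recipe")
  out <- numeric(0)
  concepts <- intersect(concepts, graph_nodes(graph, "concept"))
  if (length(recipes) == 0 || length(concepts) == 0) return(out)
  acc <- stats::setNames(numeric(length(recipes)), recipes)
  for (cpt in concepts) {
    paths <- igraph::all_simple_paths(graph$igraph, from = cpt,
                                      to = recipes, mode = "out",
                                      cutoff = max_len)
    for (p in paths) {
      end <- igraph::V(graph$igraph)$name[as.integer(p[length(p)])]
      acc[[end]] <- acc[[end]] + lambda^(length(p) - 1)
    }
  }
  acc[acc > 0]
}

#' Merge hybrid and graph signals into the candidate pool
#'
#' Ranks by the joint signal `s_hybrid + beta * s_graph` over the union
#' of hybrid-scored recipes and graph-reachable recipes (a recipe only
#' reachable through the graph still enters the pool), then truncates
#' to `pool_size`.
#'
#' @param hybrid Data frame from [hybrid_scores()] (whole corpus).
#' @param gscores Named vector from [graph_expand()].
#' @param beta Graph-signal weight (>= 0), default 0.3.
#' @param pool_size Pool truncation size, default 200.
#' @return Data frame (id, s_bm25, s_dense, s_hybrid, s_graph, s_joint)
#'   sorted by `s_joint` descending, ties by id.
#' @export
source_candidates <- function(hybrid, gscores, beta = 0.3,
                              pool_size = 200) {
  if (beta < 0) stop_config("beta", "be >= 0")
  df <- hybrid
  df$s_graph <- unname(ifelse(df$id %in% names(gscores),
                              gscores[df$id], 0))
  extra <- setdiff(names(gscores), df$id)
  if (length(extra) > 0) {
    df <- rbind(df, data.frame(id = extra, s_bm25 = 0, s_dense = 0,
                               s_hybrid = 0,
                               s_graph = as.numeric(gscores[extra]),
                               stringsAsFactors = FALSE))
  }
  df$s_joint <- df$s_hybrid + beta * df$s_graph
  df <- df[order(-df$s_joint, df$id), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, pool_size)
}
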