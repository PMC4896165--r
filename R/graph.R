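#' Undirected graphs on a set of factors
#'
#' A graphical log-linear model is indexed by an undirected graph whose
#' vertices are the factors; its interaction terms are exactly the complete
#' subsets of the graph. `llgraph()` builds a graph from an edge list,
#' [parse_model()] from generator notation such as `"ABCD+AFG+E"`.
#'
#' @param labels Character vector of vertex (factor) labels.
#' @param edges Two-column matrix (integer indices or labels) of edges, or
#'   `NULL` for the edgeless graph. Self-loops are rejected; duplicate edges
#'   are stored once.
#' @return An object of class `llgraph`.
#' @examples
#' llgraph(LETTERS[1:4], rbind(c("A", "B"), c("C", "D")))
#' @export
llgraph <- function(labels, edges = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) abort("vertex labels must be unique")
  P <- length(labels)
  if (is.null(edges) || NROW(edges) == 0) {
    e <- matrix(integer(0), 0, 2)
  } else {
    e <- as.matrix(edges)
    if (ncol(e) != 2) abort("`edges` must have two columns")
    if (is.character(e)) {
      e <- matrix(match(e, labels), ncol = 2)
      if (any(is.na(e))) abort("edge label not among vertex labels")
    }
    storage.mode(e) <- "integer"
    if (any(e < 1 | e > P)) abort("edge index out of range")
    if (any(e[, 1] == e[, 2])) abort("self-loops are not allowed")
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- unique(e)
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    dimnames(e) <- NULL
  }
  structure(list(labels = labels, edges = e), class = "llgraph")
}

#' @export
print.llgraph <- function(x, ...) {
  cat("<llgraph> ", length(x$labels), " vertices, ", nrow(x$edges),
      " edges: ", format_model(x), "\n", sep = "")
  invisible(x)
}

graph_key <- function(g) {
  paste0("g", paste(edge_id(g$edges, length(g$labels)), collapse = ","))
}

# position of each edge among the H = P(P-1)/2 unordered pairs
edge_id <- function(e, P) {
  if (nrow(e) == 0) return(integer(0))
  sort((e[, 1] - 1L) * P - (e[, 1] * (e[, 1] + 1L)) %/% 2L + e[, 2])
}

all_pairs <- function(P) {
  if (P < 2) return(matrix(integer(0), 0, 2))
  t(combn(P, 2))
}

#' Complement edge set of a graph
#' @param g An [llgraph()].
#' @return Two-column integer matrix of vertex pairs not joined by an edge.
#' @export
non_edges <- function(g) {
  P <- length(g$labels)
  ap <- all_pairs(P)
  if (nrow(g$edges) == 0) return(ap)
  keep <- !(paste(ap[, 1], ap[, 2]) %in% paste(g$edges[, 1], g$edges[, 2]))
  ap[keep, , drop = FALSE]
}

add_edge <- function(g, e) {
  llgraph(g$labels, rbind(g$edges, e))
}

remove_edge <- function(g, e) {
  e <- c(min(e), max(e))
  keep <- !(g$edges[, 1] == e[1] & g$edges[, 2] == e[2])
  llgraph(g$labels, g$edges[keep, , drop = FALSE])
}

#' Parse generator ('+'-separated clique) model notation
#'
#' Each '+'-separated token names a complete subset of the graph; tokens are
#' sequences of single-character labels (`"ABCD+AFG"`) or `.`-separated
#' multi-character labels (`"x.1.x.2"` is not supported; use single-character
#' labels or pass cliques as a list to [graph_from_cliques()]).
#' Singleton tokens add isolated vertices and may be omitted: vertices in
#' `labels` absent from every token are isolated.
#'
#' @param text Model string, e.g. `"ABCD+AFG+E"`.
#' @param labels Vertex labels (single characters).
#' @return An [llgraph()].
#' @export
parse_model <- function(text, labels) {
  if (any(nchar(labels) != 1)) {
    abort("parse_model() needs single-character labels; see graph_from_cliques()")
  }
  toks <- strsplit(trimws(strsplit(text, "+", fixed = TRUE)[[1]]), "")
  cliques <- lapply(toks, function(ch) {
    i <- match(ch, labels)
    if (any(is.na(i))) abort(paste0("unknown factor '", ch[is.na(i)][1], "'"))
    i
  })
  graph_from_cliques(cliques, labels)
}

#' Build a graph whose maximal cliques contain the given vertex sets
#' @param cliques List of integer or character vectors; each becomes complete.
#' @param labels Vertex labels.
#' @return An [llgraph()].
#' @export
graph_from_cliques <- function(cliques, labels) {
  edges <- matrix(integer(0), 0, 2)
  for (cl in cliques) {
    if (is.character(cl)) cl <- match(cl, labels)
    if (length(cl) >= 2) edges <- rbind(edges, t(combn(as.integer(cl), 2)))
  }
  llgraph(labels, edges)
}

#' Express a graph in generator notation
#' @param g An [llgraph()].
#' @return A string such as `"ABCD+AFG+E"` listing maximal cliques (isolated
#'   vertices as singletons), each clique's labels concatenated.
#' @export
format_model <- function(g) {
  cl <- maximal_cliques(g)
  cl <- cl[order(-lengths(cl), vapply(cl, function(i) paste(g$labels[i], collapse = ""), ""))]
  paste(vapply(cl, function(i) paste(g$labels[sort(i)], collapse = ""), ""),
        collapse = "+")
}

maximal_cliques <- function(g) {
  P <- length(g$labels)
  ig <- igraph::make_empty_graph(n = P, directed = FALSE)
  if (nrow(g$edges) > 0) ig <- igraph::add_edges(ig, t(g$edges))
  lapply(igraph::max_cliques(ig), function(v) sort(as.integer(v)))
}

#' Interaction terms of a graphical model
#'
#' Enumerates all non-empty complete subsets of the graph: maximal cliques
#' are found first (Bron-Kerbosch, via igraph), then closed under taking
#' subsets and deduplicated. Every singleton is always present (main effects
#' are never dropped).
#'
#' @param g An [llgraph()].
#' @return List of sorted integer vectors, ordered by size then
#'   lexicographically by the labels involved.
#' @examples
#' complete_subsets(parse_model("ABC", LETTERS[1:3]))
#' @export
complete_subsets <- function(g) {
  P <- length(g$labels)
  seen <- new.env(parent = emptyenv())
  for (cl in maximal_cliques(g)) {
    k <- length(cl)
    for (sz in seq_len(k)) {
      sub <- if (sz == k) list(cl) else combn(cl, sz, simplify = FALSE)
      for (s in sub) assign(paste(s, collapse = "."), s, envir = seen)
    }
  }
  for (p in seq_len(P)) assign(as.character(p), p, envir = seen)
  terms <- mget(ls(seen), envir = seen)
  lab <- vapply(terms, function(i) paste(g$labels[i], collapse = ""), "")
  terms <- terms[order(lengths(terms), lab)]
  names(terms) <- vapply(terms, function(i) paste(g$labels[i], collapse = ":"), "")
  terms
}
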