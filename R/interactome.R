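#' Read a protein-interaction edge list
#'
#' Two-column TSV `gene_a<TAB>gene_b`; an optional third column (e.g. an
#' interaction type or score) is ignored, as are `#` comment lines. No header
#' is expected.
#'
#' @param path Path to the edge-list file.
#' @return A two-column character data frame with columns `gene_a`, `gene_b`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", colClasses = "character",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) {
    stop(sprintf("%s: expected at least two tab-separated columns", path),
         call. = FALSE)
  }
  data.frame(gene_a = raw[[1]], gene_b = raw[[2]], stringsAsFactors = FALSE)
}

#' Build an undirected protein interactome
#'
#' Interactions are treated as undirected; self-loops are dropped and
#' duplicate edges (including reversed duplicates) are collapsed, yielding a
#' simple graph.
#'
#' @param edge_list Two-column data frame or character matrix of gene pairs.
#' @return An [igraph::igraph] object with named vertices.
#' @export
build_graph <- function(edge_list) {
  if (is.data.frame(edge_list)) edge_list <- as.matrix(edge_list[, 1:2])
  storage.mode(edge_list) <- "character"
  if (nrow(edge_list) == 0) {
    stop("empty edge list", call. = FALSE)
  }
  if (any(!nzchar(edge_list)) || anyNA(edge_list)) {
    stop("edge endpoints must be non-empty identifiers", call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(edge_list, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Extract the largest connected component
#'
#' Restricting to the largest connected component (LCC) guarantees that all
#' shortest-path distances used by the proximity measures are finite. Ties in
#' component size are broken deterministically towards the component
#' containing the lexicographically smallest vertex name.
#'
#' @param g An igraph graph with named vertices.
#' @return The induced subgraph on the largest component (a connected igraph).
#' @export
largest_connected_component <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    anchor <- vapply(best, function(b) {
      min(igraph::V(g)$name[comp$membership == b])
    }, character(1))
    best <- best[order(anchor)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Shortest-path distance oracle
#'
#' Wraps a (connected) interactome with a lazily filled cache of single-source
#' breadth-first distance maps. Sources are cached because proximity scoring
#' queries the same herb genes against many disease gene sets.
#'
#' @param g A connected igraph graph with named vertices (typically the LCC).
#' @return A `distance_oracle` object.
#' @export
distance_oracle <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  if (!igraph::is_connected(g)) {
    stop("distance oracle requires a connected graph; extract the LCC first",
         call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$graph <- g
  env$nodes <- igraph::V(g)$name
  env$cache <- new.env(parent = emptyenv())
  structure(env, class = "distance_oracle")
}

#' @export
print.distance_oracle <- function(x, ...) {
  cat(sprintf("<distance_oracle> %d nodes, %d edges, %d cached source(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(ls(x$cache))))
  invisible(x)
}

oracle_nodes <- function(oracle) oracle$nodes

# Distance matrix rows for `from` against columns `to`, filling the cache.
oracle_distances <- function(oracle, from, to) {
  stopifnot(inherits(oracle, "distance_oracle"))
  missing <- setdiff(c(from, to), oracle$nodes)
  if (length(missing) > 0) {
    stop(sprintf("node(s) absent from interactome: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  todo <- from[!vapply(from, exists, logical(1), envir = oracle$cache)]
  if (length(todo) > 0) {
    d <- igraph::distances(oracle$graph, v = todo, algorithm = "unweighted")
    for (i in seq_along(todo)) {
      assign(todo[i], d[i, oracle$nodes], envir = oracle$cache)
    }
  }
  out <- do.call(rbind, lapply(from, get, envir = oracle$cache))
  rownames(out) <- from
  out[, to, drop = FALSE]
}

#' Shortest path length between two genes
#'
#' Exact unweighted breadth-first shortest-path distance on the interactome
#' behind the oracle; finite because the oracle's graph is connected.
#'
#' @param oracle A [distance_oracle()].
#' @param a,b Gene identifiers (must be nodes of the interactome).
#' @return Non-negative integer distance; `shortest_path_length(o, a, a)` is 0.
#' @export
shortest_path_length <- function(oracle, a, b) {
  as.integer(oracle_distances(oracle, a, b)[1, 1])
}

#' Degree statistics of an interactome
#'
#' @param g An igraph graph.
#' @return A list with `mean` (2E/N), `min` and `max` node degree.
#' @export
degree_summary <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(g)
  list(mean = 2 * igraph::ecount(g) / igraph::vcount(g),
       min = min(deg), max = max(deg))
}
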