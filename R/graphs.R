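# ---------------------------------------------------------------------------
# Undirected simple graphs as node/edge-list structures -- the same arrays
# that the phase records serialize, so graphs flow through the data model
# unchanged.
# ---------------------------------------------------------------------------

#' Construct an undirected simple graph
#'
#' @param nodes Character vector of node ids (unique).
#' @param edges Two-column matrix or list of 2-element vectors; stored
#'   canonically (rows sorted, no self-loops or duplicates).
#' @return An object of class `ness_graph` with elements `nodes` and
#'   `edges`.
#' @export
ness_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("graph node ids must be unique")
  edges <- canonical_edges(edges)
  if (nrow(edges) > 0 && !all(c(edges) %in% nodes)) {
    stop("edge endpoints must be graph nodes")
  }
  structure(list(nodes = nodes, edges = edges), class = "ness_graph")
}

#' @export
print.ness_graph <- function(x, ...) {
  cat(sprintf("<ness_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a graph
#'
#' @param graph A [ness_graph()].
#' @return Named integer vector of degrees (all nodes, including isolates).
#' @export
graph_degrees <- function(graph) {
  d <- setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges) > 0) {
    tab <- table(c(graph$edges))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Adjacency list of a graph
#'
#' @param graph A [ness_graph()].
#' @return Named list: node id -> character vector of neighbor ids.
#' @export
adjacency_list <- function(graph) {
  adj <- setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (v in graph$nodes) adj[[v]] <- character(0)
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  adj
}

#' Read / write a graph as edge-list CSV
#'
#' The CSV has columns `a`,`b` (one undirected edge per row); isolated
#' nodes are preserved through the `nodes` argument on read.
#'
#' @param graph A [ness_graph()] (for writing).
#' @param path CSV file path.
#' @param nodes Optional full node set for reading (defaults to the nodes
#'   appearing in edges).
#' @return `write_edgelist_csv` returns `path` invisibly;
#'   `read_edgelist_csv` returns a [ness_graph()].
#' @export
write_edgelist_csv <- function(graph, path) {
  utils::write.csv(as.data.frame(graph$edges), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_csv
#' @export
read_edgelist_csv <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  edges <- as.matrix(df[, c("a", "b"), drop = FALSE])
  if (is.null(nodes)) nodes <- sort(unique(c(edges)))
  ness_graph(nodes, edges)
}

default_node_ids <- function(n, prefix = "v", offset = 0L) {
  sprintf("%s%d", prefix, seq_len(n) + offset)
}

#' Ring (clustered) lattice on n nodes
#'
#' Each node is linked to its `k/2` nearest neighbors on each side of a
#' ring, giving a k-regular clustered lattice with `n*k/2` edges -- the
#' high-clustering arm of the two-network contagion experiment.
#'
#' @param n Number of nodes.
#' @param k Even degree, `k < n`.
#' @param nodes Optional node ids (defaults to `v1..vn`).
#' @return A [ness_graph()].
#' @export
make_ring_lattice <- function(n, k, nodes = NULL) {
  if (k %% 2 != 0) stop("ring lattice requires an even degree k")
  if (k >= n || k < 2) stop("ring lattice requires 2 <= k < n")
  if (is.null(nodes)) nodes <- default_node_ids(n)
  stopifnot(length(nodes) == n)
  edges <- do.call(rbind, lapply(seq_len(k / 2), function(j) {
    cbind(nodes, nodes[(seq_len(n) - 1 + j) %% n + 1])
  }))
  ness_graph(nodes, edges)
}

#' Random k-regular graph via the pairing model
#'
#' Draws a simple k-regular graph by repeatedly pairing node stubs (k per
#' node) and rejecting matchings that contain self-loops or multi-edges,
#' up to `max_tries` attempts.
#'
#' @param n Number of nodes (`n*k` must be even).
#' @param k Degree, `k < n`.
#' @param seed Integer seed for the matching draw; `NULL` continues the
#'   current RNG stream.
#' @param nodes Optional node ids (defaults to `v1..vn`).
#' @param max_tries Rejection budget before giving up with an error.
#' @return A [ness_graph()], identical for identical `(n, k, seed, nodes)`.
#' @export
make_random_regular <- function(n, k, seed = NULL, nodes = NULL,
                                max_tries = 1e5) {
  if ((n * k) %% 2 != 0) stop("n * k must be even for a k-regular graph")
  if (k >= n || k < 1) stop("random regular graph requires 1 <= k < n")
  if (is.null(nodes)) nodes <- default_node_ids(n)
  stopifnot(length(nodes) == n)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    stubs <- sample(rep(seq_len(n), each = k))
    a <- stubs[seq(1, length(stubs), by = 2)]
    b <- stubs[seq(2, length(stubs), by = 2)]
    if (any(a == b)) next
    key <- pmin(a, b) * n + pmax(a, b)  # numeric edge key, exact for n*k < 2^26
    if (anyDuplicated(key)) next
    lo <- pmin(a, b); hi <- pmax(a, b)
    return(ness_graph(nodes, cbind(nodes[lo], nodes[hi])))
  }
  stop(sprintf("failed to draw a simple %d-regular graph in %d tries",
               k, max_tries))
}

#' Graph from a phase record's node/edge arrays
#'
#' @param phase A [phase_record()].
#' @return A [ness_graph()] over the phase's nodes and edges.
#' @export
phase_graph <- function(phase) {
  ness_graph(phase$nodes, phase$edges)
}
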