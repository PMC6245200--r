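# Internal helpers around the igraph container: all embedding and
# evaluation functions require a simple, undirected, single-component graph.

check_network <- function(graph, arg = "graph") {
  if (!igraph::is_igraph(graph)) {
    stop(sprintf("`%s` must be an igraph object", arg), call. = FALSE)
  }
  if (igraph::is_directed(graph)) {
    stop(sprintf("`%s` must be undirected", arg), call. = FALSE)
  }
  if (any(igraph::which_loop(graph)) || any(igraph::which_multiple(graph))) {
    stop(sprintf("`%s` must be simple (no self-loops or multi-edges); see igraph::simplify()", arg),
         call. = FALSE)
  }
  if (!igraph::is_connected(graph)) {
    stop(sprintf("`%s` is disconnected; extract the largest connected component first (see read_edgelist() or igraph::largest_component())", arg),
         call. = FALSE)
  }
  invisible(graph)
}

node_ids <- function(graph) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(graph))) else nm
}

# Degree ranks: rank 1 = highest degree, ties broken by ascending vertex
# index (stable for reproducibility across runs).
degree_ranks <- function(graph) {
  deg <- igraph::degree(graph)
  ord <- order(-deg, seq_along(deg))
  rank <- integer(length(deg))
  rank[ord] <- seq_along(deg)
  list(rank = rank, order = ord, degree = deg)
}

# Coordinates aligned to graph vertices: accepts a tibble/data.frame with
# columns node, r, theta and returns a list(r, theta) in vertex order.
align_coords <- function(coords, graph) {
  stopifnot(is.data.frame(coords), all(c("node", "r", "theta") %in% names(coords)))
  ids <- node_ids(graph)
  idx <- match(ids, as.character(coords$node))
  if (anyNA(idx)) {
    stop("coordinate table is missing nodes present in the graph", call. = FALSE)
  }
  list(r = coords$r[idx], theta = coords$theta[idx])
}
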