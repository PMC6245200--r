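#' Read a network from a plain-text edge list
#'
#' Parses a file with one edge per line (two whitespace/tab-separated node
#' identifiers; further columns, e.g. weights, are ignored). Lines starting
#' with `#` and blank lines are skipped. The input is symmetrized if
#' declared directed, self-loops and duplicate edges are dropped, and only
#' the largest connected component is kept — the preprocessing every
#' embedding method here requires.
#'
#' @param path Path to the edge-list file.
#' @param directed_input Treat lines as directed arcs and symmetrize
#'   (default `FALSE`; the result is always undirected).
#' @return An igraph object with original identifiers as vertex names.
#' @export
read_edgelist <- function(path, directed_input = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no edge records in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(toks) < 2)
  if (length(bad) > 0) {
    stop(sprintf("unparsable edge record at line %d of %s", idx[bad[1]], path),
         call. = FALSE)
  }
  el <- cbind(vapply(toks, `[[`, character(1), 1),
              vapply(toks, `[[`, character(1), 2))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  }
  g
}

#' Write an edge list
#'
#' @param graph An igraph object.
#' @param path Output path; two tab-separated columns of vertex names.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Write a node-coordinate table
#'
#' Three tab-separated columns (`node`, `r`, `theta`) with a header line
#' and full double precision, so that [read_coords()] round-trips the
#' values exactly. Angles are normalized to `[0, 2*pi)` on write.
#'
#' @param coords A data frame with columns `node`, `r`, `theta` (e.g. from
#'   [tidy.hyperbolic_embedding()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(coords, path) {
  stopifnot(is.data.frame(coords),
            all(c("node", "r", "theta") %in% names(coords)))
  if (any(coords$r < 0)) stop("negative radial coordinate", call. = FALSE)
  th <- normalize_angle(coords$theta)
  writeLines(c("node\tr\ttheta",
               sprintf("%s\t%.17g\t%.17g", coords$node, coords$r, th)),
             path)
  invisible(path)
}

#' Read a node-coordinate table
#'
#' @param path Path to a file written by [write_coords()] (header plus
#'   `node`/`r`/`theta` columns).
#' @param degrees Interpret the angular column as degrees and convert to
#'   radians (default `FALSE`).
#' @return A tibble with columns `node` (character), `r`, `theta` (radians
#'   in `[0, 2*pi)`).
#' @export
read_coords <- function(path, degrees = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("no coordinate records in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[-1]), "\\s+")
  bad <- which(lengths(toks) < 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed coordinate record at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  node <- vapply(toks, `[[`, character(1), 1)
  r <- as.numeric(vapply(toks, `[[`, character(1), 2))
  theta <- as.numeric(vapply(toks, `[[`, character(1), 3))
  if (anyNA(r) || anyNA(theta)) {
    stop(sprintf("non-numeric coordinate at line %d of %s",
                 which(is.na(r) | is.na(theta))[1] + 1L, path), call. = FALSE)
  }
  if (any(r < 0)) {
    stop(sprintf("negative radial coordinate at line %d of %s",
                 which(r < 0)[1] + 1L, path), call. = FALSE)
  }
  if (degrees) theta <- theta * pi / 180
  tibble::tibble(node = node, r = r, theta = normalize_angle(theta))
}

#' Generate a PS-network fixture on disk
#'
#' Simulates one PS network and writes its edge list
#' (`<prefix>_edges.tsv`) and ground-truth coordinate table
#' (`<prefix>_coords.tsv`). Deterministic for a fixed seed.
#'
#' @inheritParams sample_ps
#' @param out_prefix Path prefix for the two output files.
#' @return The `ps_network` object, invisibly, with the file paths in
#'   `$files`.
#' @export
make_fixture <- function(out_prefix, n, m, gamma = 2.5, temp = 0, seed = 1) {
  net <- sample_ps(n, m = m, gamma = gamma, temp = temp, seed = seed)
  files <- c(edges = paste0(out_prefix, "_edges.tsv"),
             coords = paste0(out_prefix, "_coords.tsv"))
  write_edgelist(net$graph, files[["edges"]])
  write_coords(net$coords, files[["coords"]])
  net$files <- files
  invisible(net)
}

#' Generate the benchmark grid of PS fixtures
#'
#' Writes one fixture per combination of `gammas` and `temps` (default: the
#' 3 x 4 benchmark grid at N = 500, average degree 10) under `dir`.
#'
#' @param dir Output directory (created if missing).
#' @param n,m Network size and links per node.
#' @param gammas,temps Parameter grids.
#' @param seed Base seed; configuration `q` uses `seed + q - 1`.
#' @return A tibble describing the generated fixtures.
#' @export
make_benchmark_grid <- function(dir, n = 500, m = 5,
                                gammas = c(2.25, 2.5, 2.75),
                                temps = c(0, 0.3, 0.6, 0.9), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(gamma = gammas, temp = temps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(q) {
    g <- grid$gamma[q]; tp <- grid$temp[q]
    prefix <- file.path(dir, sprintf("ps_n%d_g%s_t%s", n, g, tp))
    net <- make_fixture(prefix, n = n, m = m, gamma = g, temp = tp,
                        seed = seed + q - 1)
    tibble::tibble(gamma = g, temp = tp, seed = seed + q - 1,
                   edges = net$files[["edges"]], coords = net$files[["coords"]])
  })
  dplyr::bind_rows(rows)
}

#' Export an embedded network to GraphML
#'
#' Attaches `r` and `theta` as vertex attributes and writes GraphML, for
#' inspection in external viewers.
#'
#' @param graph An igraph object.
#' @param coords Coordinate table covering the graph's vertices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_graphml <- function(graph, coords, path) {
  al <- align_coords(coords, graph)
  igraph::V(graph)$r <- al$r
  igraph::V(graph)$theta <- al$theta
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
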