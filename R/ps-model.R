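#' Simulate a popularity-similarity (PS) network with ground-truth coordinates
#'
#' Grows a network on the hyperbolic plane: node `t` is born at radius
#' `2*log(t)` and a uniform angle, older nodes fade outward according to
#' [radial_update()], and the newcomer links to `m` existing nodes — at
#' `temp = 0` to its hyperbolically nearest ones (the step-probability
#' limit), at `temp > 0` by rejection sampling with the Fermi acceptance
#' probability of [connection_probability()]. The result is scale-free with
#' degree exponent `gamma` and a clustering coefficient that decreases with
#' `temp`.
#'
#' Fractional `m` (needed to match real-network average degrees, e.g.
#' `2m = 12.22`) is honoured in expectation: each newcomer draws
#' `m_t = floor(m) + Bernoulli(m - floor(m))` links. Early nodes with fewer
#' than `m_t` predecessors connect to all of them. Radial fading uses the
#' closed form `r_s(t) = 2*beta*log(s) + 2*(1-beta)*log(t)` (the fading rule
#' applied to birth radii), so reported coordinates are the final,
#' post-fading positions at time `N`.
#'
#' @param n Number of nodes (`>= 2`).
#' @param m Expected links per new node, `>= 1` (half the target average
#'   degree); may be fractional.
#' @param gamma Degree exponent in `[2, 3]`; sets `beta = 1/(gamma - 1)`.
#' @param temp Network temperature in `[0, 1)`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `ps_network`: a list with elements `graph`
#'   (igraph, vertices named `"1".."n"` by birth rank), `coords` (tibble
#'   with columns `node`, `r`, `theta` — final coordinates), and `params`.
#' @examples
#' net <- sample_ps(100, m = 2, gamma = 2.5, temp = 0, seed = 1)
#' net
#' mean_clustering(net$graph)
#' @export
sample_ps <- function(n, m, gamma = 2.5, temp = 0, seed = NULL) {
  stopifnot(n >= 2, m >= 1, gamma >= 2, gamma <= 3, temp >= 0, temp < 1)
  if (!is.null(seed)) set.seed(seed)
  beta <- 1 / (gamma - 1)

  theta <- runif(n, 0, 2 * pi)
  frac <- m - floor(m)
  m_t <- as.integer(rep.int(floor(m), n) +
                      if (frac > 0) rbinom(n, 1L, frac) else 0L)

  el <- ps_generate_core(as.integer(n), m_t, m, beta, temp, theta)
  graph <- igraph::graph_from_edgelist(
    cbind(as.character(el$from), as.character(el$to)), directed = FALSE)
  # vertices appear in edge order; add any stragglers and sort by birth rank
  missing <- setdiff(as.character(seq_len(n)), igraph::V(graph)$name)
  if (length(missing) > 0) graph <- igraph::add_vertices(graph, length(missing), name = missing)
  graph <- igraph::permute(graph, match(igraph::V(graph)$name, as.character(seq_len(n))))

  s <- seq_len(n)
  coords <- tibble::tibble(
    node = as.character(s),
    r = beta * 2 * log(s) + (1 - beta) * 2 * log(n),
    theta = normalize_angle(theta)
  )
  structure(
    list(graph = graph, coords = coords,
         params = list(n = n, m = m, gamma = gamma, beta = beta,
                       temp = temp, seed = seed)),
    class = "ps_network"
  )
}

#' @export
print.ps_network <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "PS network: %d nodes, %d edges (m = %g, gamma = %g, T = %g)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), p$m, p$gamma, p$temp))
  invisible(x)
}

#' @export
tidy.ps_network <- function(x, ...) x$coords

#' @export
glance.ps_network <- function(x, ...) {
  tibble::tibble(
    n = igraph::vcount(x$graph), edges = igraph::ecount(x$graph),
    avg_degree = 2 * igraph::ecount(x$graph) / igraph::vcount(x$graph),
    gamma = x$params$gamma, temp = x$params$temp,
    clustering = mean_clustering(x$graph)
  )
}

#' Mean local clustering coefficient
#'
#' Average over all nodes of `2 * triangles_i / (k_i * (k_i - 1))`; nodes of
#' degree below 2 contribute 0. This is the quantity used to calibrate
#' network temperature against cold PS replicas (see
#' [estimate_temperature()]).
#'
#' @param graph An igraph object (simple, undirected).
#' @return The mean local clustering coefficient in `[0, 1]`.
#' @export
mean_clustering <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) stop("empty network", call. = FALSE)
  igraph::transitivity(graph, type = "localaverage", isolates = "zero")
}
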