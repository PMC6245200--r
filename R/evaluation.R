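# Distance used by the router: approximate formula, switching to the exact
# law of cosines whenever the approximation would undercut the radial lower
# bound |r1 - r2| (tiny angular separations).
routing_distance <- function(r1, theta1, r2, theta2) {
  dth <- angular_separation(theta1, theta2)
  x <- r1 + r2 + 2 * log(dth / 2)
  lb <- abs(r1 - r2)
  bad <- !is.finite(x) | x < lb
  if (any(bad)) {
    cosd <- cosh(r1 - r2) + sinh(r1) * sinh(r2) * 2 * sin(dth / 2)^2
    x[bad] <- acosh(pmax(cosd, 1))[bad]
  }
  x
}

#' Greedy routing of a single packet
#'
#' Forwards a packet from `source` towards `target`: each node hands the
#' packet to the neighbour hyperbolically closest to the target's
#' coordinates. Delivery succeeds when the target is reached; it fails as
#' soon as a node would return the packet to the immediately previous node
#' (the loop rule). Distance ties are broken by the smaller vertex index. A
#' hop cap of N guards against pathological cycles longer than two nodes.
#'
#' @param coords Coordinate tibble (`node`, `r`, `theta`) covering all
#'   vertices of `graph`.
#' @param graph An igraph object.
#' @param source,target Vertex ids (names or indices), `source != target`.
#' @return A list with `delivered` (logical) and `path` (vertex indices
#'   from the source to the last node reached).
#' @export
greedy_route <- function(coords, graph, source, target) {
  al <- align_coords(coords, graph)
  adj <- igraph::as_adj_list(graph)
  src <- as.integer(igraph::V(graph)[source])
  tgt <- as.integer(igraph::V(graph)[target])
  stopifnot(src != tgt)
  greedy_route_idx(al, adj, src, tgt)
}

greedy_route_idx <- function(al, adj, src, tgt) {
  n <- length(al$r)
  cur <- src
  prev <- 0L
  path <- integer(n + 1L)
  path[1L] <- src
  len <- 1L
  rt <- al$r[tgt]; tt <- al$theta[tgt]
  while (len <= n) {
    nb <- as.integer(adj[[cur]])
    if (any(nb == tgt)) {
      path[len + 1L] <- tgt
      return(list(delivered = TRUE, path = path[seq_len(len + 1L)]))
    }
    d <- routing_distance(al$r[nb], al$theta[nb], rt, tt)
    nxt <- nb[which.min(d)]          # which.min: first minimum = smallest index
    if (nxt == prev) {
      return(list(delivered = FALSE, path = path[seq_len(len)]))
    }
    prev <- cur
    cur <- nxt
    len <- len + 1L
    path[len] <- cur
  }
  list(delivered = FALSE, path = path[seq_len(len)])
}

#' Greedy-routing performance over random source-target pairs
#'
#' Samples `n_pairs` ordered source-target pairs uniformly at random (with
#' replacement, `source != target`), routes each with [greedy_route()], and
#' computes the hop stretch (greedy path length / BFS shortest-path length)
#' of successful deliveries.
#'
#' @inheritParams greedy_route
#' @param n_pairs Number of pairs (default 1000).
#' @param seed Optional seed for the pair sample.
#' @return A `routing_report` object; see [tidy.routing_report()] and
#'   [glance.routing_report()].
#' @examples
#' net <- sample_ps(100, m = 4, gamma = 2.25, temp = 0, seed = 3)
#' routing_report(net$coords, net$graph, n_pairs = 200, seed = 3)
#' @export
routing_report <- function(coords, graph, n_pairs = 1000, seed = NULL) {
  check_network(graph)
  stopifnot(n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(graph)
  al <- align_coords(coords, graph)
  adj <- igraph::as_adj_list(graph)

  src <- sample.int(n, n_pairs, replace = TRUE)
  tgt <- sample.int(n - 1L, n_pairs, replace = TRUE)
  tgt <- tgt + (tgt >= src)

  delivered <- logical(n_pairs)
  glen <- rep(NA_integer_, n_pairs)
  for (q in seq_len(n_pairs)) {
    res <- greedy_route_idx(al, adj, src[q], tgt[q])
    delivered[q] <- res$delivered
    if (res$delivered) glen[q] <- length(res$path) - 1L
  }

  slen <- rep(NA_real_, n_pairs)
  ok <- which(delivered)
  if (length(ok) > 0) {
    usrc <- sort(unique(src[ok]))
    dmat <- igraph::distances(graph, v = usrc)
    slen[ok] <- dmat[cbind(match(src[ok], usrc), tgt[ok])]
  }

  ids <- node_ids(graph)
  pairs <- tibble::tibble(
    source = ids[src], target = ids[tgt], delivered = delivered,
    greedy_length = glen, shortest_length = as.integer(slen),
    stretch = glen / slen
  )
  new_routing_report(pairs, n_pairs)
}

#' Fraction of connected pairs as a function of hyperbolic distance
#'
#' Bins all node pairs by the hyperbolic distance implied by `coords` and
#' reports, per bin, the fraction of pairs joined by an edge. For a good
#' embedding this fraction decays from near 1 at short distances to near 0
#' at long ones, mirroring the Fermi connection probability that generated
#' the network.
#'
#' @inheritParams greedy_route
#' @param bin_width Bin width in hyperbolic-distance units (default 1).
#' @return A tibble (class `connection_curve`) with columns `distance`
#'   (bin centre), `fraction_connected`, and `n_pairs`; empty bins are
#'   omitted.
#' @export
connection_probability_curve <- function(coords, graph, bin_width = 1) {
  stopifnot(igraph::vcount(graph) >= 2, bin_width > 0)
  al <- align_coords(coords, graph)
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)

  counts <- new.env(parent = emptyenv())
  links <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    x <- approx_distance_guarded(al$r[i], al$theta[i], al$r[j], al$theta[j])
    bin <- floor(x / bin_width)
    conn <- A[i, j]
    tb <- tapply(rep(1L, length(bin)), bin, sum)
    lb <- tapply(as.numeric(conn), bin, sum)
    for (k in names(tb)) {
      counts[[k]] <- (counts[[k]] %||% 0) + tb[[k]]
      links[[k]] <- (links[[k]] %||% 0) + lb[[k]]
    }
  }
  keys <- as.numeric(ls(counts))
  keys <- keys[order(keys)]
  out <- tibble::tibble(
    distance = (keys + 0.5) * bin_width,
    fraction_connected = vapply(as.character(keys), function(k)
      links[[k]] / counts[[k]], numeric(1)),
    n_pairs = vapply(as.character(keys), function(k)
      as.numeric(counts[[k]]), numeric(1))
  )
  class(out) <- c("connection_curve", class(out))
  out
}

#' Estimate a network's temperature from its clustering coefficient
#'
#' Clustering in popularity-similarity networks decays roughly linearly
#' from its cold-regime value at `T = 0` to zero at `T = 1`. The estimator
#' generates `replicas` PS networks at `T = 0` with the target's structural
#' parameters (N, average degree, gamma), averages their mean clustering
#' coefficients into the y-intercept `cbar_zero`, anchors the x-intercept
#' at `(T = 1, cbar = 0)`, and reads the temperature off this line:
#' `T = 1 - cbar_real / cbar_zero`, clamped to `[0, 1)`.
#'
#' Supply either `graph` (from which `n`, `avg_degree`, and `clustering`
#' are measured) or those values directly.
#'
#' @param graph Optional igraph object.
#' @param gamma Degree exponent; fitted with [fit_power_law_exponent()]
#'   when a graph is supplied and `gamma` is `NULL`.
#' @param n,avg_degree,clustering Structural parameters of the target
#'   network (used when `graph` is `NULL`).
#' @param replicas Number of cold PS replicas (default 10).
#' @param seed Optional seed for the replicas.
#' @return A `temperature_fit` object; see [glance.temperature_fit()].
#' @examples
#' fit <- estimate_temperature(n = 300, avg_degree = 10, gamma = 2.5,
#'                             clustering = 0.6, replicas = 2, seed = 1)
#' glance(fit)
#' @export
estimate_temperature <- function(graph = NULL, gamma = NULL, n = NULL,
                                 avg_degree = NULL, clustering = NULL,
                                 replicas = 10, seed = NULL) {
  stopifnot(replicas >= 1)
  if (!is.null(graph)) {
    check_network(graph)
    n <- igraph::vcount(graph)
    avg_degree <- mean(igraph::degree(graph))
    clustering <- mean_clustering(graph)
    if (is.null(gamma)) {
      gamma <- as.numeric(fit_power_law_exponent(igraph::degree(graph)))
    }
  }
  stopifnot(!is.null(n), !is.null(avg_degree), !is.null(clustering),
            !is.null(gamma))
  gamma <- min(max(gamma, 2), 3)
  m <- avg_degree / 2
  if (!is.null(seed)) set.seed(seed)
  cbars <- vapply(seq_len(replicas), function(q) {
    mean_clustering(sample_ps(n, m = m, gamma = gamma, temp = 0)$graph)
  }, numeric(1))
  cbar_zero <- mean(cbars)
  if (cbar_zero <= 0) stop("cold replicas have zero clustering; degenerate parameters",
                           call. = FALSE)
  t_est <- min(max(1 - clustering / cbar_zero, 0), 1 - 1e-12)
  new_temperature_fit(clustering, cbar_zero, t_est, replicas,
                      list(n = n, avg_degree = avg_degree, gamma = gamma))
}

#' Maximum-likelihood power-law exponent of a degree sequence
#'
#' Continuous Hill estimator with the half-integer correction,
#' `gamma_hat = 1 + n_tail / sum(log(k / (k_min - 0.5)))` over degrees
#' `>= k_min`, where `k_min` is chosen by minimising the Kolmogorov-Smirnov
#' distance between the empirical tail and the fitted power law.
#'
#' @param degrees Integer vector of node degrees.
#' @param k_min Optional fixed lower cutoff; chosen by KS minimisation when
#'   `NULL`.
#' @param min_tail Minimum number of tail observations required
#'   (default 50).
#' @return The fitted exponent, with attributes `k_min`, `n_tail`, and
#'   `ks`.
#' @export
fit_power_law_exponent <- function(degrees, k_min = NULL, min_tail = 50) {
  degrees <- degrees[degrees > 0]
  fit_one <- function(km) {
    tail <- sort(degrees[degrees >= km])
    nt <- length(tail)
    if (length(unique(tail)) < 2) return(NULL)  # degenerate (all-equal) tail
    denom <- sum(log(tail / (km - 0.5)))
    if (denom <= 0) return(NULL)
    alpha <- 1 + nt / denom
    cdf_model <- 1 - ((tail - 0.5) / (km - 0.5))^(1 - alpha)
    cdf_emp <- seq_len(nt) / nt
    ks <- max(abs(cdf_emp - cdf_model), abs(cdf_emp - 1 / nt - cdf_model))
    list(alpha = alpha, ks = ks, k_min = km, n_tail = nt)
  }
  if (!is.null(k_min)) {
    if (sum(degrees >= k_min) < min_tail) {
      stop(sprintf("fewer than %d observations with degree >= k_min", min_tail),
           call. = FALSE)
    }
    f <- fit_one(k_min)
    if (is.null(f)) stop("degenerate degree sequence (no spread above k_min)",
                         call. = FALSE)
  } else {
    cands <- sort(unique(degrees))
    cands <- cands[cands >= 2]
    cands <- cands[vapply(cands, function(km) sum(degrees >= km) >= min_tail,
                          logical(1))]
    if (length(cands) == 0) {
      stop(sprintf("fewer than %d observations in every candidate tail", min_tail),
           call. = FALSE)
    }
    fits <- lapply(cands, fit_one)
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (length(fits) == 0) stop("degenerate degree sequence", call. = FALSE)
    f <- fits[[which.min(vapply(fits, function(z) z$ks, numeric(1)))]]
  }
  structure(f$alpha, k_min = f$k_min, n_tail = f$n_tail, ks = f$ks)
}
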