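#' Candidate angles for the likelihood grid search
#'
#' HyperMap places the node of degree rank `i` by scoring candidate angles
#' spaced `1/i` radians apart. In full-space mode (no `center`) the grid
#' covers `[0, 2*pi)`. In refinement mode the grid covers
#' `[center - window/2, center + window/2]` (wrapped mod `2*pi`) and always
#' contains `center` itself.
#'
#' @param i Degree rank (positive integer).
#' @param window Full window width in radians, in `(0, 2*pi]`
#'   (refinement mode only).
#' @param center Centre angle in radians, or `NULL` for full-space mode.
#' @return Numeric vector of candidate angles in `[0, 2*pi)`.
#' @export
candidate_angles <- function(i, window = NULL, center = NULL) {
  stopifnot(i >= 1)
  spacing <- 1 / i
  if (is.null(center)) {
    k <- ceiling(2 * pi * i)
    return(normalize_angle((seq_len(k) - 1) * spacing))
  }
  if (is.null(window) || window <= 0) stop("window must be positive", call. = FALSE)
  if (window / 2 >= pi) {
    k <- ceiling(2 * pi * i)
    return(unique(normalize_angle(c((seq_len(k) - 1) * spacing, center))))
  }
  K <- floor(window / 2 * i + 1e-9)
  normalize_angle(center + (-K:K) * spacing)
}

#' Link-based log-likelihood of a candidate angle
#'
#' Log of the Bernoulli likelihood that the observed links/non-links
#' between the newborn node `i` and the already-placed nodes arose from the
#' Fermi connection probability:
#' `sum_j alpha_j*log(p(x_j)) + (1 - alpha_j)*log(1 - p(x_j))`, with `p`
#' clamped to `[1e-12, 1 - 1e-12]`. Distances use the approximate formula.
#'
#' @param theta_i Candidate angle of the newborn node.
#' @param r_i Radial coordinate of the newborn node (`2*log(i)`).
#' @param r_prev,theta_prev Coordinates of the already-placed nodes, with
#'   radii updated to the current time.
#' @param alpha Logical/0-1 vector: is each placed node linked to node `i`
#'   in the observed network?
#' @param R_i Current disc radius ([disc_radius()]).
#' @param temp Working temperature (`> 0`).
#' @return Scalar log-likelihood (0 when there are no placed nodes).
#' @export
link_loglikelihood <- function(theta_i, r_i, r_prev, theta_prev, alpha,
                               R_i, temp) {
  if (length(r_prev) == 0) return(0)
  x <- approx_distance_guarded(r_prev, theta_prev, r_i, theta_i)
  p <- connection_probability(x, R_i, temp)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(ifelse(as.logical(alpha), log(p), log1p(-p)))
}

#' Common-neighbours log-likelihood of a candidate angle
#'
#' Gaussian log-likelihood of the observed final common-neighbour counts
#' `n_ij` between node `i` and each placed node `j`:
#' `(i-1)*log(1/sqrt(2*pi)) - sum_j log(sigma_j) - sum_j (n_ij - mu_j)^2 / (2*sigma_j^2)`.
#'
#' Because the observed counts live in the *final* network, the model mean
#' and variance are evaluated in the final configuration (final radii and
#' disc radius). Common neighbourship through each third node `k != i, j`
#' is treated as an independent Bernoulli event:
#' `mu_j = sum_k q_k` and `sigma_j^2 = sum_k q_k*(1 - q_k)` (floored at
#' `1e-6`), where for already-placed `k` the success probability is the
#' exact product `q_k = p(x_ik)*p(x_jk)` and for not-yet-placed `k`
#' (radii in `r_unplaced`, angles unknown) it is the expectation of that
#' product over a uniform angle. With the approximate distance, the Fermi
#' probability towards a node at final radius `r` is
#' `p(dtheta) = 1/(1 + (dtheta/(a*b_k))^(1/T))` with
#' `a = 2*exp((R - r)/2)`, `b_k = exp(-r_k/2)`, whose angular mass is
#' `I = 2*a*b_k*pi*T/sin(pi*T)`; the product expectation is approximated by
#' the two-peak form `(p_j(dtheta_ij)*I_i + p_i(dtheta_ij)*I_j)/(2*pi)`,
#' capped by `min(I_i, I_j)/(2*pi)` and 1.
#'
#' @inheritParams link_loglikelihood
#' @param n_common Vector of observed final common-neighbour counts between
#'   node `i` and each placed node.
#' @param r_unplaced Final radii of the nodes not yet placed (may be empty,
#'   in which case only placed nodes contribute).
#' @param R_i Disc radius of the final configuration.
#' @param r_i,r_prev Final radial coordinates of node `i` and of the placed
#'   nodes.
#' @return Scalar log-likelihood (0 when there are no placed nodes).
#' @export
cn_loglikelihood <- function(theta_i, r_i, r_prev, theta_prev, n_common,
                             R_i, temp, r_unplaced = numeric(0)) {
  np <- length(r_prev)
  if (np == 0) return(0)
  p_i <- connection_probability(
    approx_distance_guarded(r_prev, theta_prev, r_i, theta_i), R_i, temp)
  ts <- pi * temp / sin(pi * temp)
  a_i <- 2 * exp((R_i - r_i) / 2)
  b <- exp(-r_unplaced / 2)
  w <- b^(-1 / temp)
  ll <- np * log(1 / sqrt(2 * pi))
  for (j in seq_len(np)) {
    k <- setdiff(seq_len(np), j)
    mu <- 0; s2 <- 0
    if (length(k) > 0) {
      p_jk <- connection_probability(
        approx_distance_guarded(r_prev[k], theta_prev[k], r_prev[j], theta_prev[j]),
        R_i, temp)
      q <- p_i[k] * p_jk
      mu <- sum(q)
      s2 <- sum(q * (1 - q))
    }
    if (length(r_unplaced) > 0) {
      a_j <- 2 * exp((R_i - r_prev[j]) / 2)
      dth <- angular_separation(theta_i, theta_prev[j])
      z_i <- (dth / a_i)^(1 / temp)
      z_j <- (dth / a_j)^(1 / temp)
      g_jk <- 1 / (1 + z_j * w)
      g_ik <- 1 / (1 + z_i * w)
      q <- (a_i * g_jk + a_j * g_ik) * b * ts / pi
      q <- pmin(q, min(a_i, a_j) * b * ts / pi, 1)
      mu <- mu + sum(q)
      s2 <- s2 + sum(q * (1 - q))
    }
    s2 <- max(s2, 1e-6)
    ll <- ll - 0.5 * log(s2) - (n_common[j] - mu)^2 / (2 * s2)
  }
  ll
}

# Approximate distance with the co-angular guard but no warning (hot path).
approx_distance_guarded <- function(r1, theta1, r2, theta2) {
  dth <- angular_separation(theta1, theta2)
  x <- r1 + r2 + 2 * log(dth / 2)
  zero <- dth == 0
  if (any(zero)) x[zero] <- abs(r1 - r2)[zero]
  x
}

#' Maximum-likelihood hyperbolic embedding (HyperMap, fast hybrid version)
#'
#' Replays hyperbolic growth in degree order: the node of rank `i` is born
#' at radius `2*log(i)`, older nodes fade outward, and the newcomer's angle
#' maximises a model likelihood over a candidate grid of spacing `1/i`.
#' High-degree nodes (`degree >= k_speedup`) are scored with the
#' common-neighbours likelihood ([cn_loglikelihood()]); lower-degree nodes
#' use the link-based likelihood ([link_loglikelihood()]) in a local region
#' around an initial estimate obtained from their already-placed
#' neighbours. Final radii follow [radial_from_rank()].
#'
#' When `init_angles` and `window` are supplied (refinement mode — the
#' HyperMap stage of [labne_hm_embed()]), every node's candidate search is
#' restricted to the window around its initial angle.
#'
#' @param graph An igraph object (simple, undirected, connected).
#' @param gamma Power-law degree exponent in `[2, 3]`.
#' @param temp Working temperature in `(0, 1)`; the likelihood degenerates
#'   at `temp = 0` (estimate a temperature first, see
#'   [estimate_temperature()]).
#' @param k_speedup Degree threshold of the speed-up heuristic (default 10).
#' @param init_angles Optional draft angles: a numeric vector aligned with
#'   the graph's vertex order, or a coordinate tibble with `node`/`theta`
#'   columns.
#' @param window Full width (radians) of the search window around
#'   `init_angles`; required with `init_angles`.
#' @param local_region Half-width (radians) of the search region around the
#'   neighbour-based estimate for low-degree nodes in full mode
#'   (default `pi/6`).
#' @param seed Optional seed (sets the random angle of the rank-1 node in
#'   full mode).
#' @return A `hyperbolic_embedding` object.
#' @examples
#' net <- sample_ps(80, m = 3, gamma = 2.5, temp = 0.3, seed = 2)
#' emb <- hypermap_embed(net$graph, gamma = 2.5, temp = 0.3, seed = 2)
#' glance(emb)
#' @export
hypermap_embed <- function(graph, gamma, temp, k_speedup = 10,
                           init_angles = NULL, window = NULL,
                           local_region = pi / 6, seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  check_network(graph)
  stopifnot(gamma >= 2, gamma <= 3)
  if (temp <= 0 || temp >= 1) {
    stop("`temp` must lie in (0, 1): the growth likelihood degenerates at T = 0",
         call. = FALSE)
  }
  if (!is.null(window) && is.null(init_angles)) {
    stop("`window` requires `init_angles`", call. = FALSE)
  }
  if (!is.null(init_angles) && is.null(window)) {
    stop("`init_angles` requires `window`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n <- igraph::vcount(graph)
  beta <- 1 / (gamma - 1)
  dr <- degree_ranks(graph)
  m <- mean(dr$degree) / 2

  # adjacency in rank space
  adj <- igraph::as_adj_list(graph)
  nbr <- lapply(dr$order, function(v) as.integer(dr$rank[as.integer(adj[[v]])]))

  deg_sorted <- dr$degree[dr$order]
  n_cn <- sum(deg_sorted >= k_speedup)

  ncommon <- matrix(0, 0, 0)
  if (n_cn >= 2) {
    A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
    idx <- dr$order[seq_len(n_cn)]
    ncommon <- as.matrix(Matrix::crossprod(A[, idx, drop = FALSE]))
  }

  init <- numeric(0)
  if (!is.null(init_angles)) {
    th0 <- if (is.data.frame(init_angles)) {
      align_coords(
        if ("r" %in% names(init_angles)) init_angles
        else cbind(init_angles, r = 0), graph)$theta
    } else {
      stopifnot(length(init_angles) == n)
      as.numeric(init_angles)
    }
    init <- normalize_angle(th0[dr$order])   # rank order
    stopifnot(window > 0, window <= 2 * pi)
  }

  theta1 <- runif(1, 0, 2 * pi)
  res <- hypermap_core(nbr, ncommon, as.integer(n_cn), m, beta, temp,
                       init, if (is.null(window)) 0 else window,
                       local_region, theta1)

  theta_rank <- res$theta
  coords <- tibble::tibble(
    node = node_ids(graph),
    rank = dr$rank,
    r = radial_from_rank(dr$rank, n, gamma),
    theta = theta_rank[dr$rank]
  )
  new_hyperbolic_embedding(
    method = "hypermap", coords = coords,
    params = list(gamma = gamma, temp = temp, k_speedup = k_speedup,
                  window = window, seed = seed),
    extras = list(
      loglik = sum(res$loglik),
      loglik_init = if (length(init) > 0) sum(res$loglik_center, na.rm = TRUE) else NULL,
      loglik_by_rank = res$loglik,
      loglik_center_by_rank = res$loglik_center,
      runtime = proc.time()[["elapsed"]] - t0
    )
  )
}
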