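# Independent reference implementations used as test oracles. These
# deliberately re-derive each quantity from the formulas with plain R code,
# separate from the package's production paths.

# --- greedy routing: exhaustive step-by-step simulator ----------------------

sim_hyp_dist <- function(r1, t1, r2, t2) {
  dth <- abs(t1 - t2) %% (2 * pi)
  if (dth > pi) dth <- 2 * pi - dth
  x <- r1 + r2 + 2 * log(dth / 2)
  if (!is.finite(x) || x < abs(r1 - r2)) {
    x <- acosh(max(1, cosh(r1) * cosh(r2) - sinh(r1) * sinh(r2) * cos(dth)))
  }
  x
}

greedy_sim <- function(coords, graph, s, t) {
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(graph)))
  r <- coords$r[match(ids, as.character(coords$node))]
  th <- coords$theta[match(ids, as.character(coords$node))]
  n <- igraph::vcount(graph)
  cur <- s; prev <- NA_integer_; path <- s
  for (hop in seq_len(n)) {
    nbrs <- sort(as.integer(igraph::neighbors(graph, cur)))
    if (t %in% nbrs) return(list(delivered = TRUE, path = c(path, t)))
    d <- vapply(nbrs, function(v) sim_hyp_dist(r[v], th[v], r[t], th[t]),
                numeric(1))
    nxt <- nbrs[order(d, nbrs)][1]
    if (!is.na(prev) && nxt == prev) {
      return(list(delivered = FALSE, path = path))
    }
    prev <- cur; cur <- nxt; path <- c(path, cur)
  }
  list(delivered = FALSE, path = path)
}

# --- HyperMap: unoptimised replay built on the exported likelihoods --------

hypermap_reference <- function(graph, gamma, temp, k_speedup = 10,
                               init = NULL, window = NULL,
                               local_region = pi / 6, theta1 = 0) {
  deg <- igraph::degree(graph); n <- igraph::vcount(graph)
  ord <- order(-deg, seq_len(n)); rk <- integer(n); rk[ord] <- seq_len(n)
  beta <- 1 / (gamma - 1); m <- mean(deg) / 2
  adj <- igraph::as_adj_list(graph)
  nbr <- lapply(ord, function(v) sort(rk[as.integer(adj[[v]])]))
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)[ord, ord]
  ncom <- crossprod(A)
  rf <- 2 * beta * log(1:n) + 2 * (1 - beta) * log(n)
  RN <- disc_radius(n, m, beta, temp)
  n_cn <- sum(deg[ord] >= k_speedup)
  theta <- numeric(n)
  circd <- function(a, b) { d <- abs(a - b) %% (2 * pi); pmin(d, 2 * pi - d) }
  for (i in seq_len(n)) {
    if (i == 1) {
      theta[1] <- (if (!is.null(init)) init[1] else theta1) %% (2 * pi)
      next
    }
    ri <- 2 * log(i)
    rr <- beta * 2 * log(seq_len(i - 1)) + (1 - beta) * 2 * log(i)
    Ri <- disc_radius(i, m, beta, temp)
    use_cn <- i <= n_cn
    center <- if (!is.null(init)) init[i] else NULL
    if (is.null(init) && !use_cn) {
      pnb <- nbr[[i]][nbr[[i]] < i]
      if (length(pnb) > 0) {
        grid <- candidate_angles(i)
        ll0 <- vapply(grid, function(a) {
          x <- vapply(pnb, function(j) sim_hyp_dist_noexact(rr[j], theta[j], ri, a),
                      numeric(1))
          sum(log(pmax(connection_probability(x, Ri, temp), 1e-12)))
        }, numeric(1))
        center <- grid[which.max(ll0)]
      }
    }
    cand <- if (!is.null(center)) {
      candidate_angles(i, window = if (!is.null(init)) window else 2 * local_region,
                       center = center)
    } else candidate_angles(i)
    ll <- if (use_cn) {
      vapply(cand, function(a) cn_loglikelihood(
        a, rf[i], rf[seq_len(i - 1)], theta[seq_len(i - 1)],
        ncom[i, seq_len(i - 1)], RN, temp,
        r_unplaced = if (i < n) rf[(i + 1):n] else numeric(0)), numeric(1))
    } else {
      alpha <- seq_len(i - 1) %in% nbr[[i]]
      vapply(cand, function(a) link_loglikelihood(
        a, ri, rr, theta[seq_len(i - 1)], alpha, Ri, temp), numeric(1))
    }
    best <- which(ll == max(ll))
    if (length(best) > 1 && !is.null(center)) {
      d <- circd(cand[best], center)
      best <- best[d == min(d)]
    }
    if (length(best) > 1) best <- best[which.min(cand[best])]
    theta[i] <- cand[best]
  }
  list(theta_rank = theta, order = ord, rank = rk, theta_vertex = theta[rk])
}

# plain approximate distance with the co-angular guard (no exact fallback)
sim_hyp_dist_noexact <- function(r1, t1, r2, t2) {
  dth <- abs(t1 - t2) %% (2 * pi)
  if (dth > pi) dth <- 2 * pi - dth
  if (dth == 0) return(abs(r1 - r2))
  r1 + r2 + 2 * log(dth / 2)
}

# run the package core in rank space for direct comparison to the reference
hypermap_core_direct <- function(graph, gamma, temp, k_speedup = 10,
                                 init = NULL, window = 0,
                                 local_region = pi / 6, theta1 = 0) {
  dr <- hyperembed:::degree_ranks(graph)
  adj <- igraph::as_adj_list(graph)
  nbr <- lapply(dr$order, function(v) as.integer(dr$rank[as.integer(adj[[v]])]))
  n_cn <- sum(dr$degree[dr$order] >= k_speedup)
  ncommon <- matrix(0, 0, 0)
  if (n_cn >= 2) {
    A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
    ncommon <- as.matrix(Matrix::crossprod(A[, dr$order[seq_len(n_cn)], drop = FALSE]))
  }
  hyperembed:::hypermap_core(
    nbr, ncommon, as.integer(n_cn), mean(dr$degree) / 2, 1 / (gamma - 1),
    temp, if (is.null(init)) numeric(0) else init, window, local_region, theta1)
}

# --- circular agreement -----------------------------------------------------

# Pearson correlation between angle vectors after the best global rotation
# and reflection (720-step rotation grid); embeddings are defined only up to
# these isometries.
best_rotation_cor <- function(true, inferred) {
  best <- -1
  rots <- seq(0, 2 * pi, length.out = 361)[-361]
  for (refl in c(1, -1)) {
    for (rot in rots) {
      cand <- (refl * inferred + rot) %% (2 * pi)
      cc <- suppressWarnings(cor(true, cand))
      if (is.finite(cc) && cc > best) best <- cc
    }
  }
  best
}

# --- tiny fixture builders --------------------------------------------------

path_graph <- function(n) igraph::make_graph(rbind(1:(n - 1), 2:n), directed = FALSE)

coords_tbl <- function(r, theta, node = seq_along(r)) {
  tibble::tibble(node = as.character(node), r = r, theta = theta)
}

small_test_graphs <- function() {
  list(
    ps40 = sample_ps(40, m = 3, gamma = 2.5, temp = 0, seed = 5)$graph,
    ring8 = igraph::make_ring(8),
    k4 = igraph::make_full_graph(4),
    lattice = igraph::make_lattice(c(7, 7)),
    ps50 = sample_ps(50, m = 2, gamma = 2.2, temp = 0.4, seed = 13)$graph
  )
}
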