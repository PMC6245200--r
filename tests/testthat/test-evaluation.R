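test_that("greedy routing handles adjacency, relays, and the loop rule", {
  # adjacent source and target deliver in one hop regardless of coordinates
  g <- path_graph(4)
  co <- coords_tbl(r = c(4, 3, 2, 3), theta = c(0.1, 1, 2, 3))
  res <- greedy_route(co, g, 1, 2)
  expect_true(res$delivered)
  expect_equal(res$path, c(1, 2))

  # star: leaf to leaf goes through the hub with stretch 1
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  co_star <- coords_tbl(r = c(0.5, 3, 3, 3, 3),
                        theta = c(0, 0.5, 1.5, 2.5, 3.5))
  res <- greedy_route(co_star, star, 2, 4)
  expect_true(res$delivered)
  expect_equal(res$path, c(2, 1, 4))

  # path graph with coordinates placing node 1 closest to node 4:
  # routing 2 -> 4 picks 1, node 1 can only go back, the packet is dropped
  co_trap <- coords_tbl(r = c(1, 5, 6, 1.2),
                        theta = c(0.0, 3.0, 3.1, 0.05))
  res <- greedy_route(co_trap, g, 2, 4)
  expect_false(res$delivered)
  expect_equal(res$path, c(2, 1))
})

test_that("greedy routing matches an independent simulator on small graphs", {
  set.seed(81)
  for (q in 1:6) {
    n <- sample(6:15, 1)
    g <- igraph::sample_gnp(n, 0.35)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    n <- igraph::vcount(g)
    if (n < 3) next
    co <- coords_tbl(r = runif(n, 0, 8), theta = runif(n, 0, 2 * pi))
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t) next
      a <- greedy_route(co, g, s, t)
      b <- greedy_sim(co, g, s, t)
      expect_identical(a$delivered, b$delivered)
      expect_identical(a$path, b$path)
    }
  }
})

test_that("routing reports are deterministic and isometry-invariant", {
  net <- sample_ps(200, m = 4, gamma = 2.4, temp = 0.3, seed = 15)
  r1 <- routing_report(net$coords, net$graph, n_pairs = 300, seed = 7)
  r2 <- routing_report(net$coords, net$graph, n_pairs = 300, seed = 7)
  expect_identical(tidy(r1), tidy(r2))
  expect_equal(r1$success_rate, r1$successes / r1$n_pairs)
  expect_true(all(r1$hop_stretches >= 1))
  # global rotation + reflection of all coordinates
  co_rot <- net$coords
  co_rot$theta <- (2 * pi - co_rot$theta + 1.77) %% (2 * pi)
  r3 <- routing_report(co_rot, net$graph, n_pairs = 300, seed = 7)
  expect_equal(r3$success_rate, r1$success_rate)
  expect_equal(r3$mean_stretch, r1$mean_stretch)
})

test_that("complete graphs route perfectly with any coordinates", {
  g <- igraph::make_full_graph(12)
  set.seed(9)
  co <- coords_tbl(r = runif(12, 0, 5), theta = runif(12, 0, 2 * pi))
  rep <- routing_report(co, g, n_pairs = 100, seed = 1)
  expect_equal(rep$success_rate, 1)
  expect_equal(rep$mean_stretch, 1)
})

test_that("connection curves capture the distance dependence of linking", {
  g <- igraph::make_full_graph(10)
  set.seed(10)
  co <- coords_tbl(r = runif(10, 1, 6), theta = runif(10, 0, 2 * pi))
  cv <- connection_probability_curve(co, g)
  expect_true(all(cv$fraction_connected == 1))
  expect_equal(sum(cv$n_pairs), choose(10, 2))
  # cold PS network with true coordinates: near-step behaviour
  net <- sample_ps(500, m = 5, gamma = 2.5, temp = 0, seed = 16)
  cv2 <- connection_probability_curve(net$coords, net$graph)
  expect_gt(cv2$fraction_connected[1],
            cv2$fraction_connected[nrow(cv2)])
  expect_gt(cv2$fraction_connected[1], 0.9)
  expect_lt(cv2$fraction_connected[nrow(cv2)], 0.1)
})

test_that("temperature estimation interpolates the clustering line", {
  # y-intercept: a network whose clustering equals the cold-replica mean
  f0 <- estimate_temperature(n = 150, avg_degree = 8, gamma = 2.5,
                             clustering = 0.5, replicas = 3, seed = 2)
  f1 <- estimate_temperature(n = 150, avg_degree = 8, gamma = 2.5,
                             clustering = f0$cbar_zero, replicas = 3, seed = 2)
  expect_equal(f1$t_est, 0)
  # x-intercept: zero clustering maps to T = 1 (open clamp)
  f2 <- estimate_temperature(n = 150, avg_degree = 8, gamma = 2.5,
                             clustering = 0, replicas = 3, seed = 2)
  expect_equal(f2$t_est, 1, tolerance = 1e-9)
  expect_equal(f0$t_est, 1 - 0.5 / f0$cbar_zero, tolerance = 1e-12)
  gl <- glance(f0)
  expect_named(gl, c("t_est", "cbar_real", "cbar_zero", "n_replicas"))
})

test_that("temperature estimation accepts a graph and measures it", {
  net <- sample_ps(300, m = 4, gamma = 2.5, temp = 0.5, seed = 18)
  fit <- estimate_temperature(net$graph, gamma = 2.5, replicas = 3, seed = 4)
  expect_gte(fit$t_est, 0.2)
  expect_lte(fit$t_est, 0.8)
  expect_equal(fit$cbar_real, mean_clustering(net$graph))
})

test_that("power-law exponent fitting recovers known tails", {
  set.seed(4)
  deg <- round(10 * runif(1e4)^(-1 / 1.5))   # Pareto tail, exponent 2.5
  f <- fit_power_law_exponent(deg)
  expect_gte(as.numeric(f), 2.4); expect_lte(as.numeric(f), 2.6)
  # cross-check against an independent plfit implementation
  ig <- igraph::fit_power_law(deg, implementation = "plfit")
  expect_lt(abs(as.numeric(f) - ig$alpha), 0.2)
  # degenerate input: no spread above the cutoff
  expect_error(fit_power_law_exponent(rep(5L, 200)), "degenerate")
  expect_error(fit_power_law_exponent(c(2, 3, 4)), "fewer than")
})
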