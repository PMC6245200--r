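test_that("candidate grids have spacing 1/i and honour the window", {
  expect_length(candidate_angles(4), 26)          # ceil(8*pi)
  expect_equal(candidate_angles(4)[1:3], c(0, 0.25, 0.5))
  cand <- candidate_angles(100, window = pi / 6, center = 1.0)
  expect_true(any(abs(cand - 1.0) < 1e-12))
  dth <- pmin(abs(cand - 1.0), 2 * pi - abs(cand - 1.0))
  expect_true(all(dth <= pi / 12 + 1e-9))
  expect_equal(sort(diff(sort(cand)))[1], 0.01, tolerance = 1e-12)
  # a 2*pi window is full-space coverage (plus the centre itself)
  full <- candidate_angles(7)
  wide <- candidate_angles(7, window = 2 * pi, center = 0)
  expect_true(all(full %in% wide))
  expect_error(candidate_angles(5, window = -1, center = 0), "window")
})

test_that("link log-likelihood equals the term-by-term Bernoulli product", {
  expect_equal(link_loglikelihood(1, 0, numeric(0), numeric(0), logical(0),
                                  5, 0.5), 0)
  # one connected node at the logistic midpoint contributes log(0.5):
  # place the pair at angular gap 1 and set R to their exact distance
  r_prev <- 3; th_prev <- 0; r_i <- 2; tt <- 0.4
  R <- r_prev + r_i + 2 * log(1 / 2)
  expect_equal(link_loglikelihood(1, r_i, r_prev, th_prev, TRUE, R, tt),
               log(0.5), tolerance = 1e-10)
  # 4-node toy instance against a literal evaluation
  set.seed(21)
  rp <- c(0.5, 1.8, 2.2); tp <- c(0.3, 4.0, 2.0); al <- c(TRUE, FALSE, TRUE)
  got <- link_loglikelihood(1.1, 2.6, rp, tp, al, R = 6, temp = 0.35)
  manual <- 0
  for (j in 1:3) {
    dth <- min(abs(1.1 - tp[j]), 2 * pi - abs(1.1 - tp[j]))
    x <- rp[j] + 2.6 + 2 * log(dth / 2)
    p <- min(max(1 / (1 + exp((x - 6) / 0.7)), 1e-12), 1 - 1e-12)
    manual <- manual + if (al[j]) log(p) else log(1 - p)
  }
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("common-neighbours log-likelihood matches a literal evaluation", {
  expect_equal(cn_loglikelihood(1, 0, numeric(0), numeric(0), numeric(0),
                                5, 0.5), 0)
  # 5-node toy instance: two placed nodes, two unplaced radii
  rp <- c(1.0, 2.5); tp <- c(0.2, 3.1); nij <- c(2, 0)
  run <- c(3.0, 3.4)
  R <- 6.5; tt <- 0.45
  got <- cn_loglikelihood(0.9, 2.8, rp, tp, nij, R, tt, r_unplaced = run)
  # independent evaluation straight from the documented formulas
  ts <- pi * tt / sin(pi * tt)
  fermi <- function(x) 1 / (1 + exp((x - R) / (2 * tt)))
  dist_a <- function(r1, t1, r2, t2) {
    dth <- min(abs(t1 - t2), 2 * pi - abs(t1 - t2))
    if (dth == 0) abs(r1 - r2) else r1 + r2 + 2 * log(dth / 2)
  }
  p_i <- vapply(1:2, function(j) fermi(dist_a(rp[j], tp[j], 2.8, 0.9)), numeric(1))
  manual <- 2 * log(1 / sqrt(2 * pi))
  for (j in 1:2) {
    k <- setdiff(1:2, j)
    q_placed <- p_i[k] * fermi(dist_a(rp[k], tp[k], rp[j], tp[j]))
    a_i <- 2 * exp((R - 2.8) / 2); a_j <- 2 * exp((R - rp[j]) / 2)
    b <- exp(-run / 2)
    dth <- min(abs(0.9 - tp[j]), 2 * pi - abs(0.9 - tp[j]))
    g_j <- 1 / (1 + (dth / (a_j * b))^(1 / tt))
    g_i <- 1 / (1 + (dth / (a_i * b))^(1 / tt))
    qu <- pmin((a_i * g_j + a_j * g_i) * b * ts / pi,
               min(a_i, a_j) * b * ts / pi, 1)
    mu <- q_placed + sum(qu)
    s2 <- max(q_placed * (1 - q_placed) + sum(qu * (1 - qu)), 1e-6)
    manual <- manual - 0.5 * log(s2) - (nij[j] - mu)^2 / (2 * s2)
  }
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("the embedding core reproduces an exhaustive grid-search replay", {
  # the operation IS a grid search: the oracle is an unoptimised R replay
  # built on the exported likelihood functions
  g1 <- sample_ps(12, m = 2, gamma = 2.5, temp = 0.4, seed = 31)$graph
  ref <- hypermap_reference(g1, gamma = 2.5, temp = 0.4, theta1 = 1.2345)
  core <- hypermap_core_direct(g1, gamma = 2.5, temp = 0.4, theta1 = 1.2345)
  expect_equal(core$theta, ref$theta_rank, tolerance = 1e-12)

  # denser toy exercising the common-neighbours phase (k_speedup = 4)
  g2 <- sample_ps(14, m = 4, gamma = 2.3, temp = 0.5, seed = 77)$graph
  ref2 <- hypermap_reference(g2, gamma = 2.3, temp = 0.5, k_speedup = 4,
                             theta1 = 0.5)
  core2 <- hypermap_core_direct(g2, gamma = 2.3, temp = 0.5, k_speedup = 4,
                                theta1 = 0.5)
  expect_equal(core2$theta, ref2$theta_rank, tolerance = 1e-12)

  # refinement mode
  set.seed(5)
  init <- runif(14, 0, 2 * pi)
  dr <- hyperembed:::degree_ranks(g2)
  ref3 <- hypermap_reference(g2, gamma = 2.3, temp = 0.5, k_speedup = 4,
                             init = init[dr$order], window = pi / 2)
  core3 <- hypermap_core_direct(g2, gamma = 2.3, temp = 0.5, k_speedup = 4,
                                init = init[dr$order], window = pi / 2)
  expect_equal(core3$theta, ref3$theta_rank, tolerance = 1e-12)
})

test_that("refinement stays inside the window and never worsens the score", {
  net <- sample_ps(120, m = 4, gamma = 2.5, temp = 0.4, seed = 14)
  init <- tidy(labne_embed(net$graph, gamma = 2.5))
  w <- pi / 6
  emb <- hypermap_embed(net$graph, gamma = 2.5, temp = 0.4,
                        init_angles = init, window = w, seed = 1)
  co <- tidy(emb)
  init_th <- init$theta[match(co$node, init$node)]
  dth <- pmin(abs(co$theta - init_th), 2 * pi - abs(co$theta - init_th))
  expect_true(all(dth <= w / 2 + 1e-9))
  # per-node monotone improvement over the centre angle
  ok <- !is.na(emb$loglik_center_by_rank)
  expect_true(all(emb$loglik_by_rank[ok] >= emb$loglik_center_by_rank[ok] - 1e-9))
})

test_that("rotating the initial angles rotates the refined embedding", {
  net <- sample_ps(40, m = 3, gamma = 2.5, temp = 0.4, seed = 25)
  init <- tidy(labne_embed(net$graph, gamma = 2.5))
  delta <- 1.234
  init_rot <- init
  init_rot$theta <- (init$theta + delta) %% (2 * pi)
  e1 <- hypermap_embed(net$graph, gamma = 2.5, temp = 0.4,
                       init_angles = init, window = pi / 4, seed = 2)
  e2 <- hypermap_embed(net$graph, gamma = 2.5, temp = 0.4,
                       init_angles = init_rot, window = pi / 4, seed = 2)
  d <- (tidy(e2)$theta - tidy(e1)$theta - delta) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  expect_true(all(d < 1e-6))
})

test_that("temperature zero is rejected", {
  net <- sample_ps(30, m = 2, gamma = 2.5, temp = 0.3, seed = 3)
  expect_error(hypermap_embed(net$graph, gamma = 2.5, temp = 0), "T = 0")
})

test_that("narrow windows embed faster than the full circle", {
  net <- sample_ps(200, m = 4, gamma = 2.5, temp = 0.5, seed = 9)
  init <- tidy(labne_embed(net$graph, gamma = 2.5))
  t_narrow <- system.time(hypermap_embed(net$graph, 2.5, 0.5,
                                         init_angles = init,
                                         window = pi / 36, seed = 1))[["elapsed"]]
  t_wide <- system.time(hypermap_embed(net$graph, 2.5, 0.5,
                                       init_angles = init,
                                       window = 2 * pi, seed = 1))[["elapsed"]]
  expect_lt(t_narrow, t_wide)
})

test_that("inferred distances separate connected from disconnected pairs", {
  net <- sample_ps(300, m = 5, gamma = 2.5, temp = 0.3, seed = 6)
  emb <- hypermap_embed(net$graph, gamma = 2.5, temp = 0.3, seed = 6)
  al <- hyperembed:::align_coords(tidy(emb), net$graph)
  n <- 300
  RN <- disc_radius(n, mean(igraph::degree(net$graph)) / 2, 1 / 1.5, 0.3)
  A <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  iu <- which(upper.tri(A), arr.ind = TRUE)
  d <- hyperembed:::approx_distance_guarded(al$r[iu[, 1]], al$theta[iu[, 1]],
                                            al$r[iu[, 2]], al$theta[iu[, 2]])
  conn <- A[iu]
  expect_gt(mean(conn[d < RN]), mean(conn[d > RN]))
})
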