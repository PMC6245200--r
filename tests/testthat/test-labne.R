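test_that("graph Laplacian has the defining properties", {
  p3 <- path_graph(3)
  lap <- graph_laplacian(p3)
  expect_equal(Matrix::diag(lap$D), c(1, 2, 1))
  expect_equal(as.numeric(Matrix::rowSums(lap$L)), rep(0, 3))
  expect_equal(lap$L[2, 2], 2)
  # K4 spectrum {0, 4, 4, 4}
  k4 <- igraph::make_full_graph(4)
  ev <- sort(eigen(as.matrix(graph_laplacian(k4)$L), symmetric = TRUE)$values)
  expect_equal(ev, c(0, 4, 4, 4), tolerance = 1e-12)
  # quadratic form identity x' L x = sum over edges of (x_i - x_j)^2
  g <- small_test_graphs()$ps40
  L <- as.matrix(graph_laplacian(g)$L)
  set.seed(31)
  x <- rnorm(igraph::vcount(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  expect_equal(drop(t(x) %*% L %*% x), sum((x[el[, 1]] - x[el[, 2]])^2),
               tolerance = 1e-10)
})

test_that("disconnected input is rejected with guidance", {
  g <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  expect_error(graph_laplacian(g), "largest connected component")
  expect_error(labne_embed(g, gamma = 2.5), "largest connected component")
})

test_that("both solver paths match a dense generalized-eigenproblem oracle", {
  for (g in small_test_graphs()) {
    lap <- graph_laplacian(g)
    Dd <- as.matrix(lap$D)
    # independent route: full spectrum of the non-symmetric pencil D^-1 L
    ev <- sort(Re(eigen(solve(Dd) %*% as.matrix(lap$L))$values))
    expected <- ev[ev > 1e-10 * max(diag(Dd))][1:2]
    for (meth in c("dense", "iterative")) {
      emb <- spectral_embed(g, method = meth)
      expect_equal(emb$eigenvalues, expected, tolerance = 1e-8)
      ortho <- crossprod(emb$Y, Dd %*% emb$Y)
      expect_equal(as.matrix(ortho), diag(2), tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("cycle eigenvectors recover the circular order", {
  g <- igraph::make_ring(8)
  emb <- spectral_embed(g)
  th <- angles_from_embedding(emb)
  # walking around the ring must advance monotonically around the circle
  # (up to rotation and direction)
  d <- diff(c(th, th[1]))
  d <- (d + 2 * pi) %% (2 * pi)
  expect_true(all(d < 2 * pi / 8 + 1e-6) || all(d > 2 * pi - 2 * pi / 8 - 1e-6))
})

test_that("angles are quadrant-aware and origin rows are flagged", {
  Y <- rbind(c(1, 0), c(0, -1), c(-1, -1))
  expect_equal(angles_from_embedding(Y), c(0, 3 * pi / 2, 5 * pi / 4))
  expect_warning(th <- angles_from_embedding(rbind(c(0, 0), c(1, 1))), "origin")
  expect_equal(th[1], 0)
})

test_that("re-spreading preserves circular order and is idempotent on grids", {
  expect_equal(respread_angles(c(0.1, 0.2, 0.3)), c(0, 2 * pi / 3, 4 * pi / 3))
  expect_equal(respread_angles(c(5.0, 0.5, 1.0)), c(4 * pi / 3, 0, 2 * pi / 3))
  grid <- 2 * pi * (0:9) / 10
  expect_equal(respread_angles(grid), grid)
  shuffled <- grid[c(3, 1, 7, 10, 2, 5, 4, 9, 6, 8)]
  expect_equal(respread_angles(shuffled), shuffled)
})

test_that("embedding objective beats random D-orthonormal competitors", {
  g <- small_test_graphs()$ps50
  lap <- graph_laplacian(g)
  L <- as.matrix(lap$L); d <- Matrix::diag(lap$D)
  emb <- spectral_embed(g)
  obj <- sum(diag(t(emb$Y) %*% L %*% emb$Y))
  set.seed(55)
  n <- nrow(L)
  for (q in 1:100) {
    X <- matrix(rnorm(2 * n), n, 2)
    X <- sweep(X, 2, colSums(X * d) / sum(d))      # zero D-weighted mean
    Z <- sqrt(d) * X
    Z <- qr.Q(qr(Z))
    Yr <- Z / sqrt(d)
    expect_gte(sum(diag(t(Yr) %*% L %*% Yr)), obj - 1e-9)
  }
})

test_that("LaBNE radii hit the rank endpoints and angles recover geometry", {
  net <- sample_ps(500, m = 5, gamma = 2.5, temp = 0, seed = 41)
  emb <- labne_embed(net$graph, gamma = 2.5)
  co <- tidy(emb)
  beta <- 1 / (2.5 - 1)
  expect_equal(min(co$r), 2 * (1 - beta) * log(500), tolerance = 1e-12)
  expect_equal(max(co$r), 2 * log(500), tolerance = 1e-12)
  expect_true(all(co$r[order(co$rank)] == cummax(co$r[order(co$rank)])))
  # angular agreement with the generating coordinates (up to isometry)
  th <- co$theta[match(net$coords$node, co$node)]
  expect_gte(best_rotation_cor(net$coords$theta, th), 0.9)
})

test_that("relabelling nodes leaves the embedding geometry unchanged", {
  # label invariance holds up to the deterministic tie rules (degree ties
  # are broken by vertex index, signs fixed at vertex 1), so compare the
  # geometry: identical eigenvalues and radii profile, angles equal up to
  # a global rotation/reflection
  net <- sample_ps(60, m = 3, gamma = 2.5, temp = 0, seed = 8)
  g <- net$graph
  set.seed(17)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  f1 <- labne_embed(g, gamma = 2.5)
  f2 <- labne_embed(g2, gamma = 2.5)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
  e1 <- tidy(f1); e2 <- tidy(f2)
  m12 <- match(e1$node, e2$node)
  expect_equal(sort(e1$r), sort(e2$r))
  # degree of the rank-sorted nodes is identical under both labellings
  deg1 <- igraph::degree(g)[match(e1$node, igraph::V(g)$name)]
  expect_equal(deg1[order(e1$rank)],
               igraph::degree(g2)[match(e2$node[order(e2$rank)], igraph::V(g2)$name)],
               ignore_attr = TRUE)
  expect_gte(best_rotation_cor(e1$theta, e2$theta[m12]), 0.999)
})
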