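#' Graph Laplacian and degree matrix
#'
#' Returns the combinatorial Laplacian `L = D - A` and the diagonal degree
#' matrix `D` of a simple, undirected, connected graph, as sparse
#' [Matrix::Matrix] objects.
#'
#' @param graph An igraph object.
#' @return A list with sparse matrices `L` and `D`.
#' @export
graph_laplacian <- function(graph) {
  check_network(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  d <- igraph::degree(graph)
  D <- Matrix::Diagonal(length(d), d)
  L <- D - A
  list(L = L, D = D)
}

#' Two-dimensional spectral embedding from the generalized eigenproblem
#'
#' Solves `L y = lambda D y` and returns the two eigenvectors with the
#' smallest non-zero eigenvalues, i.e. the minimiser of
#' `tr(Y' L Y)` subject to `Y' D Y = I` (after excluding the trivial
#' constant mode). Internally the problem is whitened to the symmetric form
#' `D^(-1/2) L D^(-1/2) z = lambda z` with `y = D^(-1/2) z`.
#'
#' For graphs up to `dense_limit` nodes the full symmetric spectrum is
#' computed densely; above that a block inverse-power iteration on the
#' sparse whitened Laplacian is used (Cholesky of the shifted matrix,
#' deflation of the known constant mode). Column signs are fixed so that
#' vertex 1 has a non-negative entry, making output reproducible across
#' runs and linear-algebra backends.
#'
#' @param graph An igraph object (connected, `>= 4` nodes).
#' @param method `"auto"` (dense below `dense_limit`, iterative above),
#'   `"dense"`, or `"iterative"`.
#' @param dense_limit Size threshold for the dense path (default 2000).
#' @return An object of class `spectral_embedding`: list with `Y` (N x 2
#'   matrix, columns D-orthonormal) and `eigenvalues` (the two selected
#'   generalized eigenvalues, ascending).
#' @export
spectral_embed <- function(graph, method = c("auto", "dense", "iterative"),
                           dense_limit = 2000) {
  method <- match.arg(method)
  check_network(graph)
  n <- igraph::vcount(graph)
  stopifnot(n >= 4)
  lap <- graph_laplacian(graph)
  d <- Matrix::diag(lap$D)
  dsq <- sqrt(d)
  M <- Matrix::t(lap$L / dsq) / dsq        # D^(-1/2) L D^(-1/2)
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
  tol0 <- 1e-10 * max(d)                   # trivial-mode threshold

  if (method == "auto") method <- if (n <= dense_limit) "dense" else "iterative"

  if (method == "dense") {
    es <- eigen(as.matrix(M), symmetric = TRUE)
    vals <- rev(es$values)
    vecs <- es$vectors[, rev(seq_len(n)), drop = FALSE]
    keep <- which(vals > tol0)[1:2]
    if (anyNA(keep)) stop("not enough non-trivial eigenvalues", call. = FALSE)
    lambda <- vals[keep]
    Z <- vecs[, keep, drop = FALSE]
  } else {
    res <- eigs_inverse_iteration(M, dsq, k = 2)
    lambda <- res$values
    Z <- res$vectors
    if (any(lambda <= tol0)) stop("iterative solver returned a trivial mode", call. = FALSE)
  }

  Y <- Z / dsq
  Y <- fix_signs(Y)
  structure(list(Y = Y, eigenvalues = lambda), class = "spectral_embedding")
}

# Sign convention: make the first vertex's entry non-negative per column
# (falling back to the first entry of non-negligible magnitude).
fix_signs <- function(Y) {
  for (j in seq_len(ncol(Y))) {
    col <- Y[, j]
    ref <- if (abs(col[1]) > 1e-12 * max(abs(col))) col[1] else col[which.max(abs(col))]
    if (ref < 0) Y[, j] <- -col
  }
  Y
}

# Block inverse-power iteration for the smallest non-trivial eigenpairs of
# the whitened Laplacian M (sparse, PSD, null vector D^(1/2) 1).
eigs_inverse_iteration <- function(M, dsq, k = 2, tol = 1e-12, max_iter = 500) {
  n <- nrow(M)
  v0 <- dsq / sqrt(sum(dsq^2))
  shift <- 1e-3
  fac <- Matrix::Cholesky(M + shift * Matrix::Diagonal(n), LDL = FALSE, perm = TRUE)
  nb <- min(n - 1, k + 2)
  X <- outer(seq_len(n), seq_len(nb),
             function(i, j) sin(i * j * pi / (n + 1)))
  X <- X - v0 %*% crossprod(v0, X)
  X <- qr.Q(qr(X))
  lambda <- rep(Inf, nb)
  for (it in seq_len(max_iter)) {
    X <- as.matrix(Matrix::solve(fac, X, system = "A"))
    X <- X - v0 %*% crossprod(v0, X)
    X <- qr.Q(qr(X))
    MX <- as.matrix(M %*% X)
    Tm <- crossprod(X, MX)
    Tm <- (Tm + t(Tm)) / 2
    es <- eigen(Tm, symmetric = TRUE)
    ord <- order(es$values)
    vals <- es$values[ord]
    X <- X %*% es$vectors[, ord, drop = FALSE]
    MX <- MX %*% es$vectors[, ord, drop = FALSE]
    resid <- sqrt(colSums((MX - X %*% diag(vals, nb))^2))
    if (all(resid[1:k] <= tol * max(1, max(abs(vals[1:k])))) &&
        max(abs(vals[1:k] - lambda[1:k])) <= tol) break
    lambda <- vals
  }
  list(values = vals[1:k], vectors = X[, 1:k, drop = FALSE])
}

#' Angular coordinates from a spectral embedding
#'
#' Maps each embedding row `(y1, y2)` to the quadrant-aware arctangent
#' `atan2(y2, y1)`, normalized to `[0, 2*pi)`. Rows at the origin are
#' assigned angle 0 with a warning.
#'
#' @param emb A `spectral_embedding` object or an N x 2 matrix.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
angles_from_embedding <- function(emb) {
  Y <- if (inherits(emb, "spectral_embedding")) emb$Y else as.matrix(emb)
  stopifnot(ncol(Y) == 2)
  at_origin <- Y[, 1] == 0 & Y[, 2] == 0
  if (any(at_origin)) {
    warning(sprintf("%d node(s) at the embedding origin; assigning angle 0",
                    sum(at_origin)))
  }
  theta <- atan2(Y[, 2], Y[, 1])
  theta[at_origin] <- 0
  normalize_angle(theta)
}

#' Spread angles uniformly while preserving their circular order
#'
#' The node with angular rank `k` (0-based; ties broken by position in the
#' input vector) receives angle `2*pi*k/N`. This re-adjustment removes the
#' angular crowding typical of raw spectral coordinates.
#'
#' @param theta Numeric vector of angles.
#' @return Re-spread angles in `[0, 2*pi)`.
#' @export
respread_angles <- function(theta) {
  n <- length(theta)
  ord <- order(normalize_angle(theta), seq_len(n))
  out <- numeric(n)
  out[ord] <- 2 * pi * (seq_len(n) - 1) / n
  out
}

#' Laplacian-based network embedding (LaBNE)
#'
#' The fast spectral draft embedding: radii come from the degree ranking
#' via [radial_from_rank()]; angles come from the two non-trivial
#' generalized Laplacian eigenvectors ([spectral_embed()]), converted with
#' [angles_from_embedding()] and, by default, uniformly re-spread with
#' [respread_angles()].
#'
#' @param graph An igraph object (simple, undirected, connected).
#' @param gamma Power-law degree exponent in `[2, 3]` (affects only radii);
#'   estimate it with [fit_power_law_exponent()] if unknown.
#' @param respread Apply uniform angular re-spreading (default `TRUE`;
#'   disable only for diagnostics).
#' @param ... Passed to [spectral_embed()].
#' @return A `hyperbolic_embedding` object (see [tidy.hyperbolic_embedding()]).
#' @examples
#' net <- sample_ps(120, m = 4, gamma = 2.5, temp = 0, seed = 7)
#' emb <- labne_embed(net$graph, gamma = 2.5)
#' tidy(emb)
#' @export
labne_embed <- function(graph, gamma, respread = TRUE, ...) {
  t0 <- proc.time()[["elapsed"]]
  check_network(graph)
  stopifnot(gamma >= 2, gamma <= 3)
  n <- igraph::vcount(graph)
  dr <- degree_ranks(graph)
  emb <- spectral_embed(graph, ...)
  theta <- angles_from_embedding(emb)
  if (respread) theta <- respread_angles(theta)
  coords <- tibble::tibble(
    node = node_ids(graph),
    rank = dr$rank,
    r = radial_from_rank(dr$rank, n, gamma),
    theta = theta
  )
  new_hyperbolic_embedding(
    method = "labne", coords = coords,
    params = list(gamma = gamma, respread = respread),
    extras = list(eigenvalues = emb$eigenvalues,
                  runtime = proc.time()[["elapsed"]] - t0)
  )
}
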