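# Shared fixtures, built in code. The "world" objects are memoized so the
# expensive ones (eigendecomposition, leadfield) are computed once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

## hand-built graphs (adjacency only; coords are placeholders)
graph_from_adjacency <- function(A, coords = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (is.null(coords)) coords <- matrix(seq_len(3 * nrow(A)), ncol = 3)
  graphesi:::new_source_space_graph(A, coords)
}

path_graph3 <- function() {
  memo("path3", graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
                                     coords = cbind(0:2, 0, 0)))
}

k2_graph <- function() graph_from_adjacency(rbind(c(0, 1), c(1, 0)))

random_graph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  graph_from_adjacency(A, coords = matrix(stats::rnorm(3 * n), ncol = 3))
}

## independent O(N^2 k) flip-count oracle: explicit loops, BFS by matrix power
oracle_sign_flips <- function(u, A, k, zero_tol = 1e-9) {
  n <- length(u)
  u[abs(u) <= zero_tol * max(abs(u))] <- 0
  reach <- (A != 0)
  acc <- reach
  kk <- 1
  while (kk < k) { acc <- (acc | ((acc %*% (A != 0)) != 0)); kk <- kk + 1 }
  diag(acc) <- FALSE
  total <- 0
  for (m in seq_len(n)) for (nn in seq_len(n))
    if (acc[m, nn] && u[m] * u[nn] < 0) total <- total + 1
  total / 2
}

## small benchmark world: two hemisphere caps, 32 channels
small_world <- function() {
  memo("small_world", {
    g <- make_icosphere_source_space(frequency = 6, radius = 65,
                                     hemispheres = 2)
    fwd <- synth_leadfield(g, 32, "three_sphere", seed = 2)
    basis <- normalized_graph_frequency(eigenbasis(laplacian(g)), g)
    U_low <- select_low_band(basis, P = max(32, ceiling(0.05 * g$n_nodes)))
    list(graph = g, forward = fwd, basis = basis, U_low = U_low)
  })
}

## slightly larger world for the statistical acceptance gates
gate_world <- function() {
  memo("gate_world", {
    g <- make_icosphere_source_space(frequency = 8, radius = 65,
                                     hemispheres = 2)
    fwd <- synth_leadfield(g, 32, "three_sphere", seed = 2)
    basis <- normalized_graph_frequency(eigenbasis(laplacian(g)), g)
    U_low <- select_low_band(basis, P = max(32, ceiling(0.05 * g$n_nodes)))
    list(graph = g, forward = fwd, basis = basis, U_low = U_low)
  })
}

expect_near <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)), tol)
}

## dense naive-inverse oracles, deliberately independent of the SVD-based
## implementation paths (shared by test-solvers.R and test-acceptance.R)
oracle_mne <- function(K, Y, lam)
  t(K) %*% solve(K %*% t(K) + lam * diag(nrow(K))) %*% Y

oracle_inv_sqrt <- function(M, floor_rel = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor_rel * max(e$values))
  e$vectors %*% diag(1 / sqrt(v)) %*% t(e$vectors)
}

oracle_sloreta <- function(K, Y, lam) {
  G <- solve(K %*% t(K) + lam * diag(nrow(K)))
  M <- t(K) %*% G
  oracle_inv_sqrt(M %*% K) %*% M %*% Y
}

oracle_dspm <- function(K, Y, lam) {
  G <- solve(K %*% t(K) + lam * diag(nrow(K)))
  M <- t(K) %*% G
  oracle_inv_sqrt(M %*% t(M)) %*% M %*% Y
}
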