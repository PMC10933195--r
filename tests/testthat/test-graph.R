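test_that("mesh edges become unique symmetric graph edges", {
  ## single triangle: complete graph K3
  g <- build_graph_from_mesh(diag(3), matrix(1:3, 1), "binary")
  expect_equal(as.matrix(g$adjacency),
               matrix(1, 3, 3) - diag(3), ignore_attr = TRUE)
  expect_equal(g$degree, rep(2, 3), ignore_attr = TRUE)
  expect_equal(sum(Matrix::diag(g$laplacian)), 6)

  ## two triangles sharing an edge: the shared edge counted once, 5 edges
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  g2 <- build_graph_from_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3)), "binary")
  expect_equal(Matrix::nnzero(g2$adjacency) / 2, 5)
  expect_equal(g2$adjacency[2, 3], 1)     # shared edge weight is 1, not 2
  expect_true(isSymmetric(as.matrix(g2$adjacency)))
  expect_equal(Matrix::diag(g2$adjacency), rep(0, 4), ignore_attr = TRUE)

  ## inverse-distance weighting
  g3 <- build_graph_from_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3)),
                              "inverse_distance")
  expect_equal(g3$adjacency[1, 2], 1)          # unit spacing
  expect_equal(g3$adjacency[2, 3], 1 / sqrt(2))
})

test_that("closed icosphere meshes have 3F/2 edges", {
  m <- make_icosphere(2)
  g <- build_graph_from_mesh(m$vertices, m$faces)
  expect_equal(Matrix::nnzero(g$adjacency) / 2, nrow(m$faces) * 3 / 2)
})

test_that("mesh validation rejects bad input", {
  expect_error(build_graph_from_mesh(diag(3), matrix(c(1, 2, 4), 1)),
               "out of range")
  expect_error(build_graph_from_mesh(diag(3), matrix(c(1, 2, 2), 1)),
               "degenerate")
  expect_error(build_graph_from_mesh(matrix(0, 0, 3), matrix(0, 0, 3)),
               "empty mesh")
})

test_that("laplacian is D - A with zero row sums", {
  expect_equal(as.matrix(laplacian(k2_graph())),
               rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  L <- laplacian(path_graph3())
  expect_equal(Matrix::diag(L), c(1, 2, 1), ignore_attr = TRUE)
  expect_equal(sum(Matrix::diag(L)), 4)
  g <- random_graph(10, seed = 3)
  expect_near(as.numeric(laplacian(g) %*% rep(1, 10)), rep(0, 10), 1e-12)
})

test_that("eigenbasis is ascending, orthonormal and reconstructs L", {
  b <- eigenbasis(laplacian(path_graph3()))
  expect_near(b$eigenvalues, c(0, 1, 3), 1e-10)
  U <- b$eigenvectors
  expect_near(crossprod(U), diag(3), 1e-10)

  b2 <- eigenbasis(laplacian(k2_graph()))
  expect_near(b2$eigenvalues, c(0, 2), 1e-12)
  expect_near(abs(b2$eigenvectors[, 2]), rep(1 / sqrt(2), 2), 1e-12)

  g <- random_graph(12, seed = 5)
  b3 <- eigenbasis(laplacian(g))
  rec <- b3$eigenvectors %*% diag(b3$eigenvalues) %*% t(b3$eigenvectors)
  expect_near(rec, as.matrix(laplacian(g)), 1e-8)
  ## eigenpair residual and deterministic sign convention
  for (j in seq_len(12)) {
    u <- b3$eigenvectors[, j]
    expect_near(as.numeric(laplacian(g) %*% u), b3$eigenvalues[j] * u, 1e-8)
    expect_gt(u[which(abs(u) > 1e-10)[1]], 0)
  }
  expect_error(eigenbasis(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_length(eigenbasis(laplacian(g), n_components = 4)$eigenvalues, 4)
})

test_that("neighbor sets are k-hop balls, symmetric, excluding self", {
  g <- path_graph3()
  expect_equal(neighbor_sets(g, 1), list(`1` = 2L, `2` = c(1L, 3L), `3` = 2L),
               ignore_attr = TRUE)
  expect_equal(neighbor_sets(g, 2)[[1]], c(2L, 3L))
  ## k >= diameter reaches every other node
  gr <- random_graph(8, p = 0.5, seed = 7)
  nb <- neighbor_sets(gr, 8)
  comp_sizes <- lengths(nb)
  for (m in which(comp_sizes == 7)) expect_setequal(nb[[m]], setdiff(1:8, m))
  ## symmetry
  nb2 <- neighbor_sets(gr, 2)
  for (m in seq_along(nb2)) for (n in nb2[[m]]) expect_true(m %in% nb2[[n]])
  expect_error(neighbor_sets(g, 0), ">= 1")
})

test_that("sign flip counting follows the strict-product rule", {
  g <- path_graph3()
  nb <- neighbor_sets(g, 1)
  expect_equal(sign_flip_count(rep(1, 3), nb), 0)
  expect_equal(sign_flip_count(c(1, -2, 1) / sqrt(6), nb), 2)
  expect_equal(sign_flip_count(c(1, 0, -1) / sqrt(2), nb), 0)  # zero kills flips
  expect_equal(sign_flip_count(c(1, -1) / sqrt(2), neighbor_sets(k2_graph(), 1)), 1)
  expect_error(sign_flip_count(1:4, nb), "match")
})

test_that("flip counts match a brute-force oracle on random graphs", {
  for (seed in 1:6) {
    n <- sample(4:12, 1)
    g <- random_graph(n, p = 0.45, seed = seed)
    if (sum(g$degree) == 0) next
    A <- as.matrix(g$adjacency)
    b <- eigenbasis(laplacian(g))
    for (k in 1:3) {
      nb <- neighbor_sets(g, k)
      for (j in seq_len(n)) {
        u <- b$eigenvectors[, j]
        expect_equal(sign_flip_count(u, nb), oracle_sign_flips(u, A, k),
                     info = sprintf("seed %d k %d vec %d", seed, k, j))
      }
      ## the vectorized path inside normalized_graph_frequency agrees too
      bk <- normalized_graph_frequency(b, g, k)
      expect_equal(bk$sign_flips,
                   vapply(seq_len(n), function(j)
                     as.integer(oracle_sign_flips(b$eigenvectors[, j], A, k)),
                     integer(1)))
    }
  }
})

test_that("normalized graph frequency = flips / Tr(L)", {
  g2 <- k2_graph()
  b2 <- normalized_graph_frequency(eigenbasis(laplacian(g2)), g2)
  expect_equal(b2$ngf, c(0, 0.5))
  gp <- path_graph3()
  bp <- normalized_graph_frequency(eigenbasis(laplacian(gp)), gp)
  expect_equal(bp$ngf, c(0, 0, 0.5))
  ## constant (lambda = 0) eigenvector has no flips on a connected graph
  expect_equal(bp$sign_flips[1], 0L)
  ## edgeless graph guards the division
  ge <- graph_from_adjacency(matrix(0, 3, 3))
  expect_error(normalized_graph_frequency(eigenbasis(laplacian(ge)), ge),
               "edgeless")
})

test_that("NGF tracks the eigenvalue order on an icosphere", {
  m <- make_icosphere(2, radius = 10)
  g <- build_graph_from_mesh(m$vertices, m$faces)
  b <- normalized_graph_frequency(eigenbasis(laplacian(g)), g)
  expect_gt(cor(b$ngf, seq_along(b$ngf), method = "spearman"), 0.9)
})

test_that("low-band selection keeps the P smallest NGF eigenvectors", {
  gp <- path_graph3()
  b <- normalized_graph_frequency(eigenbasis(laplacian(gp)), gp)
  ## full basis
  expect_equal(select_low_band(b, P = 3)[, ], b$eigenvectors, ignore_attr = TRUE)
  ## P = 1 on a connected graph is the constant eigenvector
  u1 <- select_low_band(b, P = 1)
  expect_near(abs(u1), matrix(1 / sqrt(3), 3, 1), 1e-10)
  ## threshold selector: ngf values (0, 0, 0.5), tau = 0.25 -> P = 2
  expect_equal(attr(select_low_band(b, ngf_threshold = 0.25), "P"), 2L)
  ## monotone in tau
  w <- gate_world()
  taus <- c(0.001, 0.01, 0.05, 0.1, 0.5)
  Ps <- vapply(taus, function(tau)
    attr(select_low_band(w$basis, ngf_threshold = tau), "P"), integer(1))
  expect_true(all(diff(Ps) >= 0))
  ## orthonormal columns and idempotent projector
  U <- select_low_band(w$basis, P = 40)
  expect_near(crossprod(U), diag(40), 1e-8)
  Pr <- tcrossprod(U)
  expect_near(Pr %*% Pr, Pr, 1e-8)
  expect_error(select_low_band(b, P = 9), "P must be")
  expect_error(select_low_band(b, ngf_threshold = -1), ">= 0")
})

test_that("GFT round trip is exact with the full basis", {
  g <- random_graph(9, seed = 11)
  b <- eigenbasis(laplacian(g))
  s <- matrix(rnorm(9 * 4), 9, 4)
  expect_near(igft(b$eigenvectors, gft(b$eigenvectors, s)), s, 1e-8)
})
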