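# The dense naive-inverse oracles live in helper-fixtures.R.

test_that("identity-leadfield closed forms come out exactly", {
  Y <- matrix(c(2, -1, 0.5, 3, 0, -2), 3, 2)
  I3 <- diag(3)
  expect_near(mne_solve(I3, Y, 0)$data, Y, 1e-10)
  expect_near(mne_solve(I3, Y, 1)$data, Y / 2, 1e-10)
  expect_near(sloreta_solve(I3, Y, 1)$data, Y / sqrt(2), 1e-10)
  expect_near(dspm_solve(I3, Y, 1)$data, Y, 1e-10)
  expect_near(sloreta_solve(I3, 0 * Y, 1)$data, 0 * Y, 1e-12)
  expect_near(dspm_solve(I3, 0 * Y, 1)$data, 0 * Y, 1e-12)
  ## MCE on identity is the elementwise soft threshold
  expect_near(mce_solve(I3, matrix(2, 3, 1), 1, tol = 1e-10)$data,
              matrix(1, 3, 1), 1e-6)
  expect_near(mce_solve(I3, matrix(0.5, 3, 1), 1)$data, matrix(0, 3, 1), 1e-10)
  ## L21 on identity is the rowwise group soft threshold
  est <- mxne_l21_solve(diag(1), matrix(c(3, 4), 1, 2), 1, tol = 1e-10)
  expect_near(est$data, matrix(c(2.4, 3.2), 1, 2), 1e-6)
})

test_that("closed-form solvers match dense naive-inverse oracles", {
  for (seed in 1:4) {
    set.seed(seed)
    C <- sample(3:6, 1); N <- sample(7:12, 1)
    K <- matrix(rnorm(C * N), C, N)
    Y <- matrix(rnorm(C * 3), C, 3)
    lam <- 0.1
    expect_near(mne_solve(K, Y, lam)$data, oracle_mne(K, Y, lam), 1e-8)
    expect_near(sloreta_solve(K, Y, lam)$data, oracle_sloreta(K, Y, lam), 1e-8)
    expect_near(dspm_solve(K, Y, lam)$data, oracle_dspm(K, Y, lam), 1e-8)
  }
  ## larger random problem from the spec example shape
  set.seed(9)
  K <- matrix(rnorm(32), 4, 8); Y <- matrix(rnorm(8), 4, 2)
  expect_near(mne_solve(K, Y, 0.1)$data, oracle_mne(K, Y, 0.1), 1e-8)
})

test_that("mne with lam = 0 refuses a singular system with guidance", {
  K <- matrix(1, 2, 3)          # rank 1, K K^T singular
  expect_error(mne_solve(K, matrix(1, 2, 1), 0), "lam > 0")
})

test_that("sLORETA standardization removes uniform amplitude bias", {
  ## rescaling K -> cK with lam -> c^2 lam rescales the estimate uniformly
  ## by 1/c: the spatial pattern is invariant
  set.seed(2)
  K <- qr.Q(qr(matrix(rnorm(25), 5)))   # orthogonal K
  Y <- matrix(rnorm(10), 5, 2)
  c0 <- 3.7
  s1 <- sloreta_solve(K, Y, 0.5)$data
  s2 <- sloreta_solve(c0 * K, Y, c0^2 * 0.5)$data
  expect_near(c0 * s2, s1, 1e-10)
})

test_that("dSPM and sLORETA (diagonal form) share support ordering", {
  set.seed(3)
  K <- matrix(rnorm(32), 4, 8)
  y <- matrix(rnorm(4), 4, 1)
  a <- dspm_solve(K, y, 0.2, standardization = "diagonal")$data
  b <- sloreta_solve(K, y, 0.2, standardization = "diagonal")$data
  ## both are positive per-source rescalings of the same M Y: equal signs
  expect_equal(sign(a), sign(b))
})

test_that("sparse solvers satisfy lambda_max and optimality certificates", {
  set.seed(4)
  K <- matrix(rnorm(60), 5, 12)
  Y <- matrix(rnorm(15), 5, 3)
  ## at lambda >= lambda_max the zero matrix is optimal
  expect_equal(mce_solve(K, Y, lambda_max(K, Y, "l1") * 1.001)$data,
               matrix(0, 12, 3), ignore_attr = TRUE)
  expect_equal(mxne_l21_solve(K, Y, lambda_max(K, Y, "l21") * 1.001)$data,
               matrix(0, 12, 3), ignore_attr = TRUE)
  ## subgradient conditions at a converged solution
  lam <- 0.2 * lambda_max(K, Y, "l1")
  est <- mce_solve(K, Y, lam, tol = 1e-12, max_iter = 5000)
  G <- crossprod(K, Y - K %*% est$data)       # = lam * sign(S) on support
  on <- est$data != 0
  tol_cert <- 1e-4 * max(abs(crossprod(K, Y)))
  expect_lt(max(abs(G[on] - lam * sign(est$data[on]))), tol_cert)
  expect_lt(max(abs(G[!on])), lam + tol_cert)
  lam2 <- 0.2 * lambda_max(K, Y, "l21")
  est2 <- mxne_l21_solve(K, Y, lam2, tol = 1e-12, max_iter = 5000)
  G2 <- crossprod(K, Y - K %*% est2$data)
  rn <- sqrt(rowSums(est2$data^2))
  for (i in which(rn > 0))
    expect_near(G2[i, ], lam2 * est2$data[i, ] / rn[i], tol_cert)
  for (i in which(rn == 0))
    expect_lt(sqrt(sum(G2[i, ]^2)), lam2 + tol_cert)
})

test_that("FISTA objective is monotone non-increasing and flags max_iter", {
  set.seed(5)
  K <- matrix(rnorm(80), 8, 10)
  Y <- matrix(rnorm(24), 8, 3)
  lam <- 0.05 * lambda_max(K, Y, "l1")
  fit <- graphesi:::fista(K, Y, lam, graphesi:::prox_l1,
                          function(S) lam * sum(abs(S)),
                          tol = 1e-10, max_iter = 300)
  expect_true(all(diff(fit$objectives) <= 1e-12))
  est <- mce_solve(K, Y, lam, tol = 1e-16, max_iter = 3L)
  expect_false(est$convergence$converged)   # flag, not an exception
})

test_that("L21 with a single time point reduces exactly to MCE", {
  set.seed(6)
  K <- matrix(rnorm(40), 4, 10)
  y <- matrix(rnorm(4), 4, 1)
  lam <- 0.3 * lambda_max(K, y, "l1")
  a <- mce_solve(K, y, lam, tol = 1e-12, max_iter = 4000)$data
  b <- mxne_l21_solve(K, y, lam, tol = 1e-12, max_iter = 4000)$data
  expect_near(a, b, 1e-8)
})

test_that("GFT projection: full-basis equivalence and subspace confinement", {
  g <- random_graph(10, p = 0.5, seed = 8)
  b <- eigenbasis(laplacian(g))
  set.seed(8)
  K <- matrix(rnorm(5 * 10), 5, 10)
  Y <- matrix(rnorm(15), 5, 3)
  U <- b$eigenvectors
  ## orthogonal change of basis leaves the MNE solution unchanged
  expect_near(gft_solve("mne", K, Y, U, 0.2)$data, mne_solve(K, Y, 0.2)$data,
              1e-8)
  ## with U = I the sparse solvers are literally the originals
  lam <- 0.3 * lambda_max(K, Y, "l1")
  expect_near(gft_solve("mce", K, Y, diag(10), lam, tol = 1e-10)$data,
              mce_solve(K, Y, lam, tol = 1e-10)$data, 1e-8)
  ## the estimate lives in span(U_low)
  U_low <- U[, 1:4]
  est <- gft_solve("sloreta", K, Y, U_low, 0.2)$data
  expect_near(est - U_low %*% crossprod(U_low, est), 0 * est, 1e-8)
  expect_equal(gft_solve("dspm", K, Y, U_low, 0.2)$basis_P, 4L)
})

test_that("P = 1 on a connected graph gives spatially constant estimates", {
  m <- make_icosphere(1, radius = 10)
  g <- build_graph_from_mesh(m$vertices, m$faces)
  b <- normalized_graph_frequency(eigenbasis(laplacian(g)), g)
  U1 <- select_low_band(b, P = 1)
  set.seed(9)
  K <- matrix(rnorm(6 * g$n_nodes), 6, g$n_nodes)
  Y <- matrix(rnorm(12), 6, 2)
  est <- gft_solve("mne", K, Y, U1, 0.5)$data
  expect_near(est, matrix(colMeans(est), nrow(est), ncol(est), byrow = TRUE),
              1e-8)
})

test_that("low-band projection suppresses high-spatial-frequency noise", {
  ## smooth patch + high-NGF source-space noise over 50 seeded trials.
  ## The low band must be wide enough to carry the patch (here the lower
  ## ~30% of the spectrum); the volume conductor already attenuates
  ## high-NGF patterns strongly, so the projection gain is real but modest.
  w <- small_world()
  K <- w$forward$leadfield
  N <- w$graph$n_nodes
  U <- w$basis$eigenvectors
  hi <- U[, (N - 149):N]                      # top-NGF sub-basis
  U_low <- select_low_band(w$basis, P = 100)
  err <- matrix(NA, 50, 2)
  for (tr in 1:50) {
    set.seed(tr)
    truth <- sample_patch(w$graph, sample(N, 1), 2)
    s_true <- truth$amplitudes
    s_noisy <- s_true + hi %*% rnorm(150, sd = 1)
    Y <- K %*% s_noisy
    lam <- default_lambda(K, 30)
    err[tr, 1] <- sum((mne_solve(K, Y, lam)$data - s_true)^2)
    err[tr, 2] <- sum((gft_solve("mne", K, Y, U_low, lam)$data - s_true)^2)
  }
  expect_lte(mean(err[, 2]), mean(err[, 1]))
})

test_that("default lambda heuristics have the documented closed forms", {
  set.seed(10)
  K <- matrix(rnorm(24), 4, 6)
  expect_equal(default_lambda(K, 20), sum(K^2) / (4 * 100))
  Y <- matrix(rnorm(8), 4, 2)
  expect_equal(lambda_max(K, Y, "l1"), max(abs(t(K) %*% Y)))
  expect_equal(lambda_max(K, Y, "l21"),
               max(sqrt(rowSums((t(K) %*% Y)^2))))
})
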