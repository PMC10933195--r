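#' Build a source-space graph from a triangulated mesh
#'
#' Constructs the undirected graph whose nodes are mesh vertices and whose
#' edges are the unique triangle edges. Each shared triangle edge contributes
#' a single undirected edge, so the adjacency matrix is symmetric with zero
#' diagonal regardless of how many faces share an edge.
#'
#' @param vertices numeric matrix, N x 3, vertex coordinates in mm.
#' @param faces integer matrix, F x 3, 1-based vertex indices of each
#'   triangle (file readers convert from the 0-based on-disk convention).
#' @param weighting `"binary"` (edge weight 1) or `"inverse_distance"`
#'   (weight \eqn{1/\|x_i - x_j\|}).
#' @return A `source_space_graph`: list with `n_nodes`, `coords`,
#'   `adjacency` (sparse symmetric), `degree` (vector of row sums of A),
#'   and `laplacian` (L = D - A, sparse symmetric).
#' @examples
#' g <- build_graph_from_mesh(diag(3), matrix(1:3, 1), "binary")
#' Matrix::diag(g$laplacian)  # K3: all degrees 2
#' @export
build_graph_from_mesh <- function(vertices, faces,
                                  weighting = c("binary", "inverse_distance")) {
  weighting <- match.arg(weighting)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) == 0L || is.null(faces) || nrow(faces) == 0L)
    stop("empty mesh: need at least one vertex and one face")
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n))
    stop("face index out of range [1, ", n, "]")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
    stop("degenerate triangle: face with a repeated vertex")

  ## unique undirected edges from the three sides of every triangle
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(1, 3), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)

  w <- if (weighting == "binary") {
    rep(1, nrow(e))
  } else {
    d <- sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                         vertices[e[, 2], , drop = FALSE])^2))
    if (any(d == 0)) stop("coincident vertices give infinite inverse-distance weight")
    1 / d
  }

  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = c(w, w), dims = c(n, n))
  new_source_space_graph(A, vertices)
}

#' @keywords internal
new_source_space_graph <- function(A, coords) {
  deg <- Matrix::rowSums(A)
  L <- Matrix::Diagonal(x = deg) - A
  structure(list(n_nodes = nrow(A), coords = coords, adjacency = A,
                 degree = deg, laplacian = L),
            class = "source_space_graph")
}

#' @export
print.source_space_graph <- function(x, ...) {
  cat("<source_space_graph> ", x$n_nodes, " nodes, ",
      Matrix::nnzero(x$adjacency) / 2, " edges, Tr(L) = ",
      format(sum(x$degree)), "\n", sep = "")
  invisible(x)
}

#' Graph Laplacian of a source-space graph
#'
#' Returns L = D - A where D is the diagonal degree matrix. Row sums of L
#' are exactly zero and L is positive semi-definite.
#'
#' @param graph a `source_space_graph`.
#' @return sparse symmetric matrix L.
#' @export
laplacian <- function(graph) {
  stopifnot(inherits(graph, "source_space_graph"))
  graph$laplacian
}

#' Laplacian eigenbasis of the source-space graph
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order.
#' Each eigenvector's sign is fixed so that its first component larger than
#' 1e-10 in magnitude is positive; eigenvector sign is otherwise arbitrary
#' and this convention makes the basis reproducible across LAPACK builds.
#'
#' @param L symmetric positive semi-definite matrix (dense or sparse).
#' @param n_components `"all"` or the number of leading (smallest-eigenvalue)
#'   components to retain.
#' @return A `spectral_basis`: `eigenvalues` (ascending), `eigenvectors`
#'   (orthonormal columns). Sign-flip counts and normalized graph
#'   frequencies are filled in by [normalized_graph_frequency()].
#' @export
eigenbasis <- function(L, n_components = "all") {
  L <- as.matrix(L)
  if (!isSymmetric(L, tol = 1e-8))
    stop("L must be symmetric")
  ee <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(ee$values)           # eigen() returns descending
  lam <- ee$values[ord]
  U <- ee$vectors[, ord, drop = FALSE]
  lam[lam < 0 & lam > -1e-8] <- 0
  U <- fix_eigenvector_signs(U)
  if (!identical(n_components, "all")) {
    p <- as.integer(n_components)
    if (p < 1L || p > length(lam)) stop("n_components out of range")
    lam <- lam[seq_len(p)]
    U <- U[, seq_len(p), drop = FALSE]
  }
  structure(list(eigenvalues = lam, eigenvectors = U,
                 sign_flips = NULL, ngf = NULL, neighbor_order = NULL,
                 bands = NULL, low_basis = NULL, cutoff = NULL),
            class = "spectral_basis")
}

## first component with |u| > 1e-10 made positive, columnwise
fix_eigenvector_signs <- function(U, tol = 1e-10) {
  for (j in seq_len(ncol(U))) {
    nz <- which(abs(U[, j]) > tol)
    if (length(nz) && U[nz[1], j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat("<spectral_basis> ", length(x$eigenvalues), " eigenpairs",
      if (!is.null(x$cutoff)) paste0(", low band P = ", x$cutoff), "\n",
      sep = "")
  invisible(x)
}

#' k-hop neighbor sets
#'
#' Nodes reachable from each node in at most `order` hops, excluding the
#' node itself. Neighborhoods are symmetric: n is a neighbor of m iff m is
#' a neighbor of n.
#'
#' @param graph a `source_space_graph`.
#' @param order neighborhood order k >= 1 (1 = direct mesh neighbors).
#' @return list of integer vectors, one per node.
#' @export
neighbor_sets <- function(graph, order = 1L) {
  stopifnot(inherits(graph, "source_space_graph"))
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("order must be >= 1")
  A1 <- graph$adjacency != 0
  R <- A1
  P <- A1
  k <- 1L
  while (k < order) {
    P <- (P %*% A1) != 0
    R <- R | P
    k <- k + 1L
  }
  Matrix::diag(R) <- FALSE
  R <- as(R, "TsparseMatrix")
  split(R@i + 1L, factor(R@j + 1L, levels = seq_len(graph$n_nodes)))
}

#' Sign-flip count of a graph signal
#'
#' Counts the ordered neighbor pairs (m, n) with strictly negative product
#' u(m) * u(n) and halves the total, so each unordered pair counts once.
#' A zero component never contributes a flip.
#'
#' Components within `zero_tol * max(abs(u))` of zero are treated as exact
#' zeros, so an eigenvector with an analytically-zero node (stored with
#' rounding error) is not charged a spurious flip.
#'
#' @param u numeric vector of length N (typically a Laplacian eigenvector).
#' @param neighbors per-node neighbor sets from [neighbor_sets()].
#' @param zero_tol relative magnitude below which a component counts as zero.
#' @return nonnegative integer flip count.
#' @export
sign_flip_count <- function(u, neighbors, zero_tol = 1e-9) {
  if (length(u) != length(neighbors))
    stop("length(u) must match the number of neighbor sets")
  u[abs(u) <= zero_tol * max(abs(u))] <- 0
  pairs <- neighbor_pairs(neighbors)
  sum(u[pairs[, 1]] * u[pairs[, 2]] < 0)
}

## unordered (m < n) neighbor pairs as a 2-column matrix
neighbor_pairs <- function(neighbors) {
  m <- rep.int(seq_along(neighbors), lengths(neighbors))
  n <- unlist(neighbors, use.names = FALSE)
  keep <- m < n
  cbind(m[keep], n[keep])
}

#' Normalized graph frequency of each eigenvector
#'
#' The normalized graph frequency (NGF) of an eigenvector is its sign-flip
#' count over order-k neighbor pairs divided by the trace of the graph
#' Laplacian. On a connected graph the constant (zero-eigenvalue)
#' eigenvector has NGF 0, and NGF increases with spatial oscillation,
#' tracking the eigenvalue order.
#'
#' @param basis a `spectral_basis` from [eigenbasis()].
#' @param graph the `source_space_graph` the Laplacian came from.
#' @param order neighbor order k used for flip counting (default 1).
#' @return the basis with `sign_flips`, `ngf`, `neighbor_order` and `bands`
#'   filled in. Bands split eigenvectors into low/medium/high thirds of the
#'   NGF ordering (labels `"L"`, `"M"`, `"H"`).
#' @export
normalized_graph_frequency <- function(basis, graph, order = 1L) {
  stopifnot(inherits(basis, "spectral_basis"),
            inherits(graph, "source_space_graph"))
  trL <- sum(graph$degree)
  if (trL <= 0) stop("edgeless graph: Tr(L) = 0, NGF undefined")
  nb <- neighbor_sets(graph, order)
  pairs <- neighbor_pairs(nb)
  U <- basis$eigenvectors
  ## zero out rounding-level components (see sign_flip_count), then count
  ## strictly negative products per column in one pass
  colmax <- apply(abs(U), 2, max)
  U[abs(U) <= rep(1e-9 * colmax, each = nrow(U))] <- 0
  flips <- colSums(U[pairs[, 1], , drop = FALSE] *
                     U[pairs[, 2], , drop = FALSE] < 0)
  basis$sign_flips <- as.integer(flips)
  basis$ngf <- flips / trL
  basis$neighbor_order <- as.integer(order)
  ranks <- rank(basis$ngf, ties.method = "first")
  ncol_ <- length(ranks)
  basis$bands <- cut(ranks, breaks = c(0, ncol_ / 3, 2 * ncol_ / 3, ncol_),
                     labels = c("L", "M", "H"))
  basis
}

#' Select the low-frequency sub-basis
#'
#' Picks the P eigenvectors with the smallest normalized graph frequency,
#' ties broken by ascending eigenvalue then ascending index. With
#' `ngf_threshold`, P is the number of eigenvectors with NGF <= tau.
#'
#' @param basis a `spectral_basis` with NGF values (see
#'   [normalized_graph_frequency()]).
#' @param P number of columns to keep (ignored when `ngf_threshold` given).
#' @param ngf_threshold keep all eigenvectors with NGF <= this value.
#' @return N x P matrix with orthonormal columns; attributes `indices`
#'   (which eigenvectors) and `P`.
#' @export
select_low_band <- function(basis, P = NULL, ngf_threshold = NULL) {
  stopifnot(inherits(basis, "spectral_basis"))
  if (is.null(basis$ngf))
    stop("basis has no NGF values; run normalized_graph_frequency() first")
  n <- length(basis$eigenvalues)
  ord <- order(basis$ngf, basis$eigenvalues, seq_len(n))
  if (!is.null(ngf_threshold)) {
    if (ngf_threshold < 0) stop("ngf_threshold must be >= 0")
    P <- sum(basis$ngf <= ngf_threshold)
    if (P == 0L) stop("ngf_threshold selects no eigenvectors")
  }
  P <- as.integer(P)
  if (is.na(P) || P < 1L || P > n) stop("P must be in [1, ", n, "]")
  idx <- sort(ord[seq_len(P)])
  U_low <- basis$eigenvectors[, idx, drop = FALSE]
  attr(U_low, "indices") <- idx
  attr(U_low, "P") <- P
  U_low
}

#' Graph Fourier transform and its inverse
#'
#' `gft()` expands a source-space signal in the eigenvector basis
#' (`t(U) %*% s`); `igft()` maps coefficients back (`U %*% s_tilde`).
#'
#' @param U matrix with orthonormal columns (full basis or low band).
#' @param s signal matrix, N x T (or P x T for `igft`).
#' @return coefficient / signal matrix.
#' @export
gft <- function(U, s) crossprod(U, as.matrix(s))

#' @rdname gft
#' @export
igft <- function(U, s) U %*% as.matrix(s)
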