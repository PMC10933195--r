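#' Triangulated geodesic sphere (icosphere)
#'
#' Subdivides each face of a regular icosahedron into `frequency^2`
#' triangles on an exact integer barycentric grid (so shared edge vertices
#' are deduplicated exactly) and projects every vertex onto the sphere.
#' `subdivisions = s` corresponds to `frequency = 2^s`, giving the familiar
#' 12, 42, 162, 642, 2562 ... vertex counts; any integer frequency m is
#' accepted and yields `10 m^2 + 2` vertices and `20 m^2` faces.
#'
#' @param subdivisions recursion depth s >= 0 (used when `frequency` NULL).
#' @param radius sphere radius in mm.
#' @param frequency optional geodesic frequency m >= 1, overriding
#'   `subdivisions`; useful to hit vertex counts that are not `10*4^s + 2`.
#' @param center length-3 numeric, translation applied after scaling.
#' @return list with `vertices` (V x 3) and `faces` (F x 3, 1-based).
#' @export
make_icosphere <- function(subdivisions = 0L, radius = 1,
                           frequency = NULL, center = c(0, 0, 0)) {
  if (is.null(frequency)) {
    subdivisions <- as.integer(subdivisions)
    if (is.na(subdivisions) || subdivisions < 0L)
      stop("subdivisions must be >= 0")
    m <- 2L^subdivisions
  } else {
    m <- as.integer(frequency)
    if (is.na(m) || m < 1L) stop("frequency must be >= 1")
  }

  phi <- (1 + sqrt(5)) / 2
  base_v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0,  1), c(-phi, 0, -1), c(-phi, 0,  1))
  base_f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  ## integer barycentric grid per face; key = (corner ids, integer weights)
  key_env <- new.env(hash = TRUE, size = 16L * m * m)
  verts <- vector("list", 10L * m * m + 2L)
  n_v <- 0L
  get_vertex <- function(corners, weights) {
    nz <- weights > 0L
    o <- order(corners[nz])
    key <- paste(corners[nz][o], weights[nz][o], sep = ":", collapse = "|")
    id <- key_env[[key]]
    if (!is.null(id)) return(id)
    n_v <<- n_v + 1L
    verts[[n_v]] <<- drop(weights %*% base_v[corners, , drop = FALSE]) / m
    key_env[[key]] <- n_v
    n_v
  }

  faces <- matrix(0L, nrow = 20L * m * m, ncol = 3L)
  n_f <- 0L
  for (f in seq_len(nrow(base_f))) {
    crn <- base_f[f, ]
    ## P[r+1][c+1], r = 0..m rows away from corner A, c = 0..r
    P <- vector("list", m + 1L)
    for (r in 0:m) {
      row_ids <- integer(r + 1L)
      for (c in 0:r)
        row_ids[c + 1L] <- get_vertex(crn, c(m - r, r - c, c))
      P[[r + 1L]] <- row_ids
    }
    for (r in 1:m) {
      up <- P[[r]]; lo <- P[[r + 1L]]
      for (c in 0:(r - 1L)) {
        n_f <- n_f + 1L
        faces[n_f, ] <- c(up[c + 1L], lo[c + 1L], lo[c + 2L])
      }
      if (r >= 2L) for (c in 0:(r - 2L)) {
        n_f <- n_f + 1L
        faces[n_f, ] <- c(up[c + 1L], lo[c + 2L], up[c + 2L])
      }
    }
  }

  V <- do.call(rbind, verts[seq_len(n_v)])
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, center, "+")
  list(vertices = V, faces = faces)
}

#' Icosphere source space
#'
#' Builds a source-space graph from one or two geodesic spheres. The
#' two-hemisphere mode concatenates two disjoint meshes (no edges between
#' them), standing in for the left and right cortical surfaces.
#'
#' @inheritParams make_icosphere
#' @param hemispheres 1 or 2 disjoint meshes.
#' @param shape with two hemispheres: `"cap"` (default) splits a single
#'   cortical sphere into left and right hemispherical caps along the
#'   midsagittal plane, so every source sits at the same superficial
#'   eccentricity, like the cortical sheet under a spherical head;
#'   `"sphere"` concatenates two full spheres centered at `centers`.
#' @param centers hemisphere centers for `shape = "sphere"`,
#'   `hemispheres` x 3 matrix (mm); default `(-12, 0, 0)`, `(12, 0, 0)`.
#' @param gap half-width (mm) of the midsagittal gap removed between caps.
#' @param weighting passed to [build_graph_from_mesh()].
#' @return a `source_space_graph` with an extra `mesh` field (concatenated
#'   vertices/faces) and `metadata` (generator parameters).
#' @export
make_icosphere_source_space <- function(subdivisions = 3L, radius = 65,
                                        frequency = NULL, hemispheres = 1L,
                                        shape = c("cap", "sphere"),
                                        centers = NULL, gap = NULL,
                                        weighting = "binary") {
  hemispheres <- as.integer(hemispheres)
  shape <- match.arg(shape)
  stopifnot(hemispheres %in% c(1L, 2L))
  if (hemispheres == 2L && shape == "cap") {
    full <- make_icosphere(subdivisions, radius, frequency)
    if (is.null(gap)) gap <- 0.01 * radius
    meshes <- list(mesh_restrict(full, full$vertices[, 1] < -gap),
                   mesh_restrict(full, full$vertices[, 1] > gap))
  } else {
    if (is.null(centers))
      centers <- if (hemispheres == 1L) matrix(0, 1, 3) else
        rbind(c(-12, 0, 0), c(12, 0, 0))
    centers <- matrix(centers, ncol = 3)
    meshes <- lapply(seq_len(hemispheres), function(h)
      make_icosphere(subdivisions, radius, frequency, centers[h, ]))
  }
  nv <- vapply(meshes, function(mh) nrow(mh$vertices), integer(1))
  offset <- c(0L, cumsum(nv))[seq_len(hemispheres)]
  vertices <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  faces <- do.call(rbind, Map(function(mh, off) mh$faces + off,
                              meshes, offset))
  g <- build_graph_from_mesh(vertices, faces, weighting)
  g$mesh <- list(vertices = vertices, faces = faces)
  g$metadata <- list(generator = "icosphere", subdivisions = subdivisions,
                     frequency = frequency, radius = radius,
                     hemispheres = hemispheres, shape = shape,
                     n_vertices = nrow(vertices), n_faces = nrow(faces))
  g
}

## keep the vertices where `keep` is TRUE and the faces fully inside
mesh_restrict <- function(mesh, keep) {
  idx <- which(keep)
  remap <- integer(nrow(mesh$vertices))
  remap[idx] <- seq_along(idx)
  fkeep <- matrix(keep[mesh$faces], ncol = 3)
  faces <- mesh$faces[rowSums(fkeep) == 3L, , drop = FALSE]
  ## drop vertices that lost all their faces
  used <- sort(unique(as.vector(faces)))
  idx <- intersect(idx, used)
  remap <- integer(nrow(mesh$vertices))
  remap[idx] <- seq_along(idx)
  list(vertices = mesh$vertices[idx, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3))
}
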