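#' Synthetic leadfield generator
#'
#' Stand-in for an MRI/BEM forward pipeline. Two generators:
#'
#' * `three_sphere` — the classical three-concentric-spheres volume
#'   conductor (brain, skull, scalp shells). Each source is a radial
#'   current dipole at its vertex; the scalp potential is the axisymmetric
#'   spherical-harmonic series, with per-degree coefficients obtained by
#'   solving the boundary-condition system of the layered sphere (potential
#'   and radial current continuous at each interface, no current through
#'   the scalp). Sensors are laid out on the scalp sphere with a Fibonacci
#'   lattice.
#' * `smooth_random` — `K = G W` with i.i.d. Gaussian `G` and a few rounds
#'   of random-walk smoothing `W` on the source graph, giving spatially
#'   correlated columns without any physics.
#'
#' Units are arbitrary but consistent; SNR is defined on sensor signals so
#' units cancel.
#'
#' @param source_space a `source_space_graph` (vertex coordinates in mm,
#'   head-centered; all sources must lie inside the brain shell for
#'   `three_sphere`).
#' @param n_sensors number of channels C >= 2.
#' @param model `"three_sphere"` or `"smooth_random"`.
#' @param seed integer seed (used by `smooth_random`; recorded either way).
#' @param head_radii brain/skull/scalp shell radii, mm.
#' @param conductivities per-shell conductivities, S/m; the classical
#'   Rush-Driscoll triple (skull 1/80 of brain and scalp) by default.
#' @param cap_fraction sensors are spread over the scalp cap
#'   `z > -(2 * cap_fraction - 1) * r`; the default 0.85 approximates an
#'   EEG cap reaching below the ears but not under the head.
#' @param n_terms spherical-harmonic truncation degree.
#' @param smoothing_steps random-walk smoothing rounds for `smooth_random`.
#' @return a `forward_model`: `leadfield` (C x N), `sensor_coords` (C x 3),
#'   `source_coords` (N x 3), `metadata`.
#' @export
synth_leadfield <- function(source_space, n_sensors = 128L,
                            model = c("three_sphere", "smooth_random"),
                            seed = 1L,
                            head_radii = c(80, 85, 92),
                            conductivities = c(0.33, 0.0042, 0.33),
                            cap_fraction = 0.85,
                            n_terms = 100L, smoothing_steps = 3L) {
  model <- match.arg(model)
  stopifnot(inherits(source_space, "source_space_graph"))
  n_sensors <- as.integer(n_sensors)
  if (is.na(n_sensors) || n_sensors < 2L) stop("n_sensors must be >= 2")
  src <- source_space$coords
  sens <- fibonacci_cap(n_sensors, head_radii[3], cap_fraction)

  K <- if (model == "three_sphere") {
    three_sphere_leadfield(src, sens, head_radii, conductivities, n_terms)
  } else {
    smooth_random_leadfield(source_space, n_sensors, seed, smoothing_steps)
  }
  if (any(rowSums(abs(K)) == 0)) stop("leadfield has an all-zero row (dead sensor)")
  if (any(colSums(abs(K)) == 0)) stop("leadfield has an all-zero column (invisible source)")
  structure(list(leadfield = K, sensor_coords = sens, source_coords = src,
                 metadata = list(model = model, seed = seed,
                                 head_radii = head_radii,
                                 conductivities = conductivities,
                                 n_terms = n_terms,
                                 smoothing_steps = smoothing_steps)),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat("<forward_model> ", nrow(x$leadfield), " channels x ",
      ncol(x$leadfield), " sources (", x$metadata$model, ")\n", sep = "")
  invisible(x)
}

## Evenly spread points on the upper fraction of a sphere (golden-angle
## spiral); fraction = 1 covers the whole sphere.
fibonacci_cap <- function(n, radius = 1, fraction = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * fraction * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(theta), r * sin(theta), z) * radius
}

## Per-degree transfer coefficients g_n for the layered sphere, in units of
## the scalp radius. Unknowns per degree n: (A1, A2, B2, A3, B3) for the
## shell potentials A r^n + B r^-(n+1); the unit source term is the dipole
## singular part B1s r^-(n+1) in the inner shell. Returns the scalp-surface
## potential coefficient for B1s = 1.
three_sphere_coefs <- function(n_terms, radii, sigma) {
  r <- radii / radii[3]
  s <- sigma
  g <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    rn <- r^n; rm <- r^(-(n + 1)); rd <- n * r^(n - 1); re <- (n + 1) * r^(-(n + 2))
    M <- rbind(
      c(rn[1], -rn[1], -rm[1], 0, 0),                        # potential at r1
      c(s[1] * rd[1], -s[2] * rd[1], s[2] * re[1], 0, 0),    # current at r1
      c(0, rn[2], rm[2], -rn[2], -rm[2]),                    # potential at r2
      c(0, s[2] * rd[2], -s[2] * re[2], -s[3] * rd[2], s[3] * re[2]),  # current at r2
      c(0, 0, 0, rd[3], -re[3]))                             # no current at r3
    b <- c(-rm[1], s[1] * re[1], 0, 0, 0)
    x <- solve(M, b)
    g[n] <- x[4] * rn[3] + x[5] * rm[3]
  }
  g
}

three_sphere_leadfield <- function(src, sens, radii, sigma, n_terms) {
  b <- sqrt(rowSums(src^2))
  if (any(b >= radii[1]))
    stop("all sources must lie strictly inside the brain shell (radius ",
         radii[1], " mm)")
  if (any(b < 1e-9)) stop("source at the head center has no radial direction")
  r3 <- radii[3]
  g <- three_sphere_coefs(n_terms, radii, sigma)
  ns <- seq_len(n_terms)
  ## cos of the angle between each source direction and each sensor direction
  src_dir <- src / b
  sens_dir <- sens / sqrt(rowSums(sens^2))
  cosg <- pmin(1, pmax(-1, sens_dir %*% t(src_dir)))   # C x N
  ## Legendre P_n(cosg) accumulated against per-source coefficients
  bn <- outer(b / r3, ns - 1, `^`)                      # N x n_terms: (b/r3)^(n-1)
  coef <- t(bn * rep(ns * g, each = nrow(src)))         # n_terms x N
  C <- nrow(sens); N <- nrow(src)
  K <- matrix(0, C, N)
  Pnm1 <- matrix(1, C, N)      # P_0
  Pn <- cosg                   # P_1
  K <- K + Pn * rep(coef[1, ], each = C)
  for (n in 2:n_terms) {
    Pnext <- ((2 * n - 1) * cosg * Pn - (n - 1) * Pnm1) / n
    Pnm1 <- Pn; Pn <- Pnext
    K <- K + Pn * rep(coef[n, ], each = C)
  }
  K / (4 * pi * sigma[1] * r3^2)
}

smooth_random_leadfield <- function(source_space, n_sensors, seed, steps) {
  N <- source_space$n_nodes
  G <- with_seed(seed, matrix(stats::rnorm(n_sensors * N), n_sensors, N))
  W <- source_space$adjacency + Matrix::Diagonal(N)
  W <- W / Matrix::rowSums(W)
  K <- G
  for (i in seq_len(steps)) K <- as.matrix(K %*% W)
  K
}

#' Read / write a leadfield matrix
#'
#' Text container: tab-separated values, one row per channel, preceded by
#' header comment lines `# graphesi leadfield` and `# channels C sources N`.
#' Binary container: magic bytes `GESI`, int32 version, int32 C and N, then
#' C*N doubles in column-major order (documented, byte-exact round trip).
#' Sensor/source coordinates, when present, travel in `<path>.sensors.tsv`
#' and `<path>.sources.tsv` sidecars.
#'
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @param source_space optional `source_space_graph`; when given, the
#'   number of sources must match its node count.
#' @return `read_leadfield`: a `forward_model` (coords NULL if no sidecars).
#' @export
read_leadfield <- function(path, format = c("text", "binary"),
                           source_space = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("leadfield file not found: ", path)
  if (format == "text") {
    hdr <- readLines(path, n = 2L)
    if (!startsWith(hdr[1], "# graphesi leadfield"))
      stop("not a graphesi leadfield text file")
    dims <- as.integer(strsplit(hdr[2], "\\s+")[[1]][c(3, 5)])
    K <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
    dimnames(K) <- NULL
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    magic <- readChar(con, 4L, useBytes = TRUE)
    if (!identical(magic, "GESI")) stop("not a graphesi leadfield binary file")
    readBin(con, "integer", 1L)                       # version
    dims <- readBin(con, "integer", 2L)
    K <- matrix(readBin(con, "double", prod(dims)), dims[1], dims[2])
  }
  if (!all(dim(K) == dims)) stop("leadfield shape header inconsistent with data")
  if (!is.null(source_space) && ncol(K) != source_space$n_nodes)
    stop("leadfield has ", ncol(K), " sources but the source space has ",
         source_space$n_nodes)
  read_coords <- function(p) if (file.exists(p))
    as.matrix(utils::read.table(p, sep = "\t")) else NULL
  structure(list(leadfield = K,
                 sensor_coords = read_coords(paste0(path, ".sensors.tsv")),
                 source_coords = read_coords(paste0(path, ".sources.tsv")),
                 metadata = list(model = "file", path = path)),
            class = "forward_model")
}

#' @rdname read_leadfield
#' @param model a `forward_model` (or plain C x N matrix) to write.
#' @export
write_leadfield <- function(model, path, format = c("text", "binary")) {
  format <- match.arg(format)
  K <- if (inherits(model, "forward_model")) model$leadfield else as.matrix(model)
  if (format == "text") {
    con <- file(path, "w")
    writeLines(c("# graphesi leadfield",
                 sprintf("# channels %d sources %d", nrow(K), ncol(K))), con)
    utils::write.table(format(K, digits = 17, trim = TRUE), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
  } else {
    con <- file(path, "wb")
    writeChar("GESI", con, eos = NULL)
    writeBin(c(1L, nrow(K), ncol(K)), con)
    writeBin(as.vector(K), con)
    close(con)
  }
  if (inherits(model, "forward_model")) {
    wc <- function(x, p) if (!is.null(x))
      utils::write.table(format(x, digits = 17, trim = TRUE), p, sep = "\t",
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    wc(model$sensor_coords, paste0(path, ".sensors.tsv"))
    wc(model$source_coords, paste0(path, ".sources.tsv"))
  }
  invisible(path)
}

## Run expr with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
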