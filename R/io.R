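#' Read / write sensor measurements
#'
#' Tab-separated text, one row per channel, preceded by a
#' `# sampling_rate <Hz>` header line.
#'
#' @param path file path.
#' @return `read_measurement`: a `measurement`.
#' @export
read_measurement <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# sampling_rate"))
    stop("missing '# sampling_rate' header in ", path)
  fs <- as.numeric(strsplit(hdr, "\\s+")[[1]][3])
  Y <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(Y) <- NULL
  if (!all(is.finite(Y))) stop("non-finite entries in measurement file")
  new_measurement(Y, fs)
}

#' @rdname read_measurement
#' @param m a `measurement` (or plain C x T matrix).
#' @param fs sampling rate when `m` is a plain matrix.
#' @export
write_measurement <- function(m, path, fs = 100) {
  if (inherits(m, "measurement")) { Y <- m$data; fs <- m$sampling_rate }
  else Y <- as.matrix(m)
  con <- file(path, "w")
  writeLines(sprintf("# sampling_rate %g Hz", fs), con)
  utils::write.table(format(Y, digits = 17, trim = TRUE), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Write a source estimate with a JSON provenance sidecar
#'
#' The estimate matrix goes to `<path>` in the measurement text dialect;
#' method, lambda, basis size and convergence info go to `<path>.json`.
#'
#' @param estimate a `source_estimate`.
#' @param path output path.
#' @param fs sampling rate recorded in the header.
#' @export
write_estimate <- function(estimate, path, fs = 100) {
  stopifnot(inherits(estimate, "source_estimate"))
  write_measurement(estimate$data, path, fs)
  jsonlite::write_json(
    list(method = estimate$method, variant = estimate$variant,
         lam = estimate$lam, basis_P = estimate$basis_P,
         convergence = estimate$convergence),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export / import a spectral basis
#'
#' Text container: a `# graphesi basis N P` header, one line of
#' eigenvalues, one line of NGF values (or `NA`s), then the eigenvector
#' matrix row by row, tab-separated. Binary container: magic `GESB`,
#' int32 version/N/P, doubles for eigenvalues, NGF and U (column-major).
#'
#' @param basis a `spectral_basis`.
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @export
write_basis <- function(basis, path, format = c("text", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(basis, "spectral_basis"))
  U <- basis$eigenvectors
  ngf <- basis$ngf %||% rep(NA_real_, ncol(U))
  if (format == "text") {
    con <- file(path, "w")
    writeLines(sprintf("# graphesi basis %d %d", nrow(U), ncol(U)), con)
    writeLines(paste(format(basis$eigenvalues, digits = 17), collapse = "\t"), con)
    writeLines(paste(format(ngf, digits = 17), collapse = "\t"), con)
    utils::write.table(format(U, digits = 17, trim = TRUE), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
  } else {
    con <- file(path, "wb")
    writeChar("GESB", con, eos = NULL)
    writeBin(c(1L, nrow(U), ncol(U)), con)
    writeBin(c(basis$eigenvalues, as.double(ngf), as.vector(U)), con)
    close(con)
  }
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("basis file not found: ", path)
  if (format == "text") {
    lines <- readLines(path)
    dims <- as.integer(strsplit(lines[1], "\\s+")[[1]][4:5])
    lam <- scan(text = lines[2], quiet = TRUE)
    ngf <- suppressWarnings(as.numeric(strsplit(lines[3], "\t")[[1]]))
    U <- matrix(scan(text = lines[-(1:3)], quiet = TRUE),
                nrow = dims[1], byrow = TRUE)
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    magic <- readChar(con, 4L, useBytes = TRUE)
    if (!identical(magic, "GESB")) stop("not a graphesi basis file")
    readBin(con, "integer", 1L)
    dims <- readBin(con, "integer", 2L)
    lam <- readBin(con, "double", dims[2])
    ngf <- readBin(con, "double", dims[2])
    U <- matrix(readBin(con, "double", prod(dims)), dims[1], dims[2])
  }
  if (all(is.na(ngf))) ngf <- NULL
  structure(list(eigenvalues = lam, eigenvectors = U, sign_flips = NULL,
                 ngf = ngf, neighbor_order = NULL, bands = NULL,
                 low_basis = NULL, cutoff = NULL),
            class = "spectral_basis")
}
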