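#' Read a triangle mesh from OFF or Wavefront OBJ
#'
#' Both formats store 0-based (OFF) or 1-based (OBJ) vertex indices; the
#' returned faces are 1-based. Only pure triangle meshes are accepted.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"off"`, `"obj"` or `"auto"`.
#' @return list with `vertices` (N x 3, mm) and `faces` (F x 3, 1-based).
#' @export
read_mesh <- function(path, format = c("auto", "off", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", obj = "obj",
                     stop("cannot infer mesh format from extension '", ext, "'"))
  }
  if (format == "off") read_off(path) else read_obj(path)
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!identical(lines[1], "OFF")) stop("not an OFF file (missing OFF header)")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (nv < 1 || nf < 1) stop("empty mesh in OFF file")
  vtx <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  fl <- lapply(lines[(3 + nv):(2 + nv + nf)],
               function(s) scan(text = s, quiet = TRUE))
  if (any(vapply(fl, function(f) f[1] != 3, logical(1))))
    stop("OFF mesh contains non-triangle faces")
  faces <- t(vapply(fl, function(f) as.integer(f[2:4]), integer(3))) + 1L
  list(vertices = vtx, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("empty mesh in OBJ file")
  vtx <- matrix(scan(text = gsub("^v ", "", vl), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  parse_face <- function(s) {
    toks <- strsplit(trimws(sub("^f ", "", s)), "\\s+")[[1]]
    if (length(toks) != 3) stop("OBJ mesh contains non-triangle faces")
    as.integer(vapply(strsplit(toks, "/"), `[`, character(1), 1))
  }
  faces <- t(vapply(fl, parse_face, integer(3)))
  dimnames(faces) <- NULL
  list(vertices = vtx, faces = faces)
}

#' Write a triangle mesh to OFF
#'
#' @param vertices N x 3 matrix. @param faces F x 3 matrix of 1-based indices.
#' @param path output file.
#' @export
write_off <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(vertices), nrow(faces), 0L), con)
  utils::write.table(format(vertices, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
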