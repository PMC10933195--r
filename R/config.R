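config_defaults <- function() {
  list(
    ## geometry / forward
    subdivisions = 3L, frequency = NULL, radius = 55, hemispheres = 2L,
    n_sensors = 128L, forward_model = "three_sphere",
    ## basis
    neighbor_order = 1L, P = NULL, ngf_threshold = NULL,
    ## solver
    method = "mne", gft = TRUE, lam = NULL, rho = 0.1,
    standardization = "matrix", tol = 1e-6, max_iter = 1000L,
    ## scenario
    kind = "patch", ln_level = 1L, snr_db = 40, n_trials = 200L,
    T = NULL, fs = 100, waveform = "gauss_sine",
    ar = list(order = 1L, n_active = 2L, spectral_radius = 0.9, noise_sd = 1),
    filter = list(low = 0.1, high = 40, order = 3L),
    ## bookkeeping
    seed = 1L, verbosity = 1L, out = NULL,
    leadfield = NULL, data = NULL, basis = NULL)
}

#' Parse a run configuration
#'
#' Reads an optional JSON config file, overlays explicit overrides (CLI
#' flags win over file values, which win over the documented defaults) and
#' rejects unknown keys with a nearest-match suggestion.
#'
#' @param path optional JSON config file.
#' @param overrides named list of values taking precedence over the file.
#' @return fully resolved named list of settings (class `run_config`).
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  apply_keys <- function(cfg, vals, origin) {
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown)) {
      hint <- vapply(unknown, function(k) {
        dist <- utils::adist(k, names(cfg))
        cand <- names(cfg)[which.min(dist)]
        if (min(dist) <= 3) sprintf(" (did you mean '%s'?)", cand) else ""
      }, character(1))
      stop("unknown config key", if (length(unknown) > 1) "s", " in ", origin,
           ": ", paste0("'", unknown, "'", hint, collapse = ", "),
           "\nvalid keys: ", paste(names(cfg), collapse = ", "))
    }
    for (k in names(vals)) cfg[[k]] <- vals[[k]]
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- apply_keys(cfg, vals, path)
  }
  cfg <- apply_keys(cfg, overrides, "command line")
  structure(cfg, class = c("run_config", "list"))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

save_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}
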