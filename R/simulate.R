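#' Extended-patch ground truth
#'
#' Activates a contiguous cortical patch: the center vertex at relative
#' amplitude 1.0 and the rings of vertices at exact hop distance r = 1..k
#' at 80%, 60% and 40% of the center amplitude. Vertices beyond hop k stay
#' at zero.
#'
#' @param graph a `source_space_graph`.
#' @param center center vertex index (1-based).
#' @param ln_level neighborhood level k in 1..3.
#' @param ring_amplitudes relative amplitudes of rings 1..3.
#' @return a `ground_truth`: `amplitudes` (length N), `active_set`,
#'   `center_index`; `S_true` is filled in by [build_trial()].
#' @export
sample_patch <- function(graph, center, ln_level,
                         ring_amplitudes = c(0.8, 0.6, 0.4)) {
  stopifnot(inherits(graph, "source_space_graph"))
  ln_level <- as.integer(ln_level)
  if (ln_level < 1L || ln_level > length(ring_amplitudes))
    stop("ln_level must be in 1..", length(ring_amplitudes))
  center <- as.integer(center)
  if (is.na(center) || center < 1L || center > graph$n_nodes)
    stop("center index out of range [1, ", graph$n_nodes, "]")
  hops <- hop_distances(graph, center, ln_level)
  amp <- numeric(graph$n_nodes)
  amp[center] <- 1
  for (r in seq_len(ln_level)) amp[hops == r] <- ring_amplitudes[r]
  if (sum(amp > 0) == 1L && graph$degree[center] == 0)
    warning("isolated center vertex: only the center is active")
  structure(list(amplitudes = amp, active_set = which(amp > 0),
                 center_index = center, ln_level = ln_level, S_true = NULL),
            class = "ground_truth")
}

## hop distance from `center`, capped at kmax + 1 (Inf beyond)
hop_distances <- function(graph, center, kmax) {
  d <- rep(Inf, graph$n_nodes)
  d[center] <- 0
  frontier <- center
  A <- graph$adjacency
  for (r in seq_len(kmax)) {
    nb <- unique(A[, frontier, drop = FALSE]@i + 1L)
    nb <- nb[is.infinite(d[nb])]
    if (!length(nb)) break
    d[nb] <- r
    frontier <- nb
  }
  d
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> center ", x$center_index, ", level ", x$ln_level,
      ", ", length(x$active_set), " active sources\n", sep = "")
  invisible(x)
}

#' Patch activation waveform
#'
#' `gauss_sine` is a unit-peak sinusoid under a Gaussian envelope (carrier
#' frequency and phase drawn per seed); `const` is all ones.
#'
#' @param kind `"gauss_sine"` or `"const"`.
#' @param T number of samples. @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return numeric vector of length `T`, peak magnitude 1.
#' @export
make_waveform <- function(kind = c("gauss_sine", "const"), T = 100L,
                          fs = 100, seed = 1L) {
  kind <- match.arg(kind)
  if (T < 1L) stop("T must be >= 1")
  if (kind == "const") return(rep(1, T))
  t <- (seq_len(T) - 1) / fs
  par <- with_seed(seed, c(stats::runif(1, 8, 12), stats::runif(1, 0, 2 * pi)))
  t0 <- t[ceiling(T / 2)]
  w <- sin(2 * pi * par[1] * t + par[2]) * exp(-(t - t0)^2 / (2 * (0.12)^2))
  w / max(abs(w))
}

#' Add sensor noise at a target SNR
#'
#' Adds i.i.d. Gaussian noise scaled so that
#' \eqn{10 \log_{10}(P_{signal}/P_{noise})} equals `snr_db` exactly, with
#' power defined as the mean squared amplitude over all channel-time
#' entries (the realization is rescaled to the exact target power, so the
#' empirical SNR of every generated dataset matches the target).
#'
#' @param Y_clean noise-free sensor matrix, C x T (nonzero).
#' @param snr_db target SNR in dB; `Inf` returns `Y_clean` unchanged.
#' @param seed integer seed.
#' @param fs sampling rate stored on the result, Hz.
#' @return a `measurement`: `data` (C x T), `sampling_rate`, `channel_ids`.
#' @export
add_sensor_noise <- function(Y_clean, snr_db, seed = 1L, fs = 100) {
  Y_clean <- as.matrix(Y_clean)
  p_sig <- mean(Y_clean^2)
  if (p_sig == 0) stop("Y_clean is all zeros: SNR undefined")
  if (is.infinite(snr_db) && snr_db > 0) {
    Y <- Y_clean
  } else {
    p_noise <- p_sig / 10^(snr_db / 10)
    E <- with_seed(seed, matrix(stats::rnorm(length(Y_clean)),
                                nrow(Y_clean), ncol(Y_clean)))
    E <- E * sqrt(p_noise / mean(E^2))
    Y <- Y_clean + E
  }
  new_measurement(Y, fs)
}

#' @keywords internal
new_measurement <- function(Y, fs = 100, channel_ids = NULL) {
  structure(list(data = Y, sampling_rate = fs,
                 channel_ids = channel_ids %||% paste0("ch", seq_len(nrow(Y)))),
            class = "measurement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.measurement <- function(x, ...) {
  cat("<measurement> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Random stationary autoregressive model
#'
#' Transition matrices are drawn entrywise from Uniform(-1, 1) and rescaled
#' so the companion-form spectral radius equals `spectral_radius`,
#' guaranteeing stationarity.
#'
#' @param n_active number of coupled source channels (default 2).
#' @param order AR order (default 1).
#' @param spectral_radius target companion spectral radius in (0, 1).
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed.
#' @return an `ar_model`: list of `transition` matrices (one per lag),
#'   `order`, `n_active`, `noise_sd`, `seed`.
#' @export
rand_ar_model <- function(n_active = 2L, order = 1L, spectral_radius = 0.9,
                          noise_sd = 1, seed = 1L) {
  stopifnot(spectral_radius > 0, spectral_radius < 1)
  Phi <- with_seed(seed, lapply(seq_len(order), function(k)
    matrix(stats::runif(n_active^2, -1, 1), n_active, n_active)))
  rho <- companion_spectral_radius(Phi)
  if (rho > 0) {
    ## scaling lag k by c^k scales every companion eigenvalue by c
    sc <- spectral_radius / rho
    Phi <- lapply(seq_len(order), function(k) Phi[[k]] * sc^k)
  }
  structure(list(transition = Phi, order = as.integer(order),
                 n_active = as.integer(n_active), noise_sd = noise_sd,
                 seed = seed),
            class = "ar_model")
}

companion_spectral_radius <- function(Phi) {
  p <- length(Phi); d <- nrow(Phi[[1]])
  Cm <- matrix(0, p * d, p * d)
  Cm[seq_len(d), ] <- do.call(cbind, Phi)
  if (p > 1) Cm[(d + 1):(p * d), seq_len((p - 1) * d)] <- diag((p - 1) * d)
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

#' Generate autoregressive source time series
#'
#' Runs the vector-AR recursion \eqn{x_t = \sum_k \Phi_k x_{t-k} + n_t}
#' with Gaussian innovations, discarding a 100-sample burn-in.
#'
#' @param model an `ar_model` (see [rand_ar_model()]).
#' @param T output length after burn-in.
#' @param seed integer seed.
#' @param burn_in samples discarded at the start.
#' @return `n_active` x `T` matrix.
#' @export
gen_ar_sources <- function(model, T, seed = 1L, burn_in = 100L) {
  stopifnot(inherits(model, "ar_model"))
  if (companion_spectral_radius(model$transition) >= 1)
    stop("AR model is not stationary (companion spectral radius >= 1)")
  d <- model$n_active; p <- model$order
  total <- T + burn_in
  X <- matrix(0, d, total + p)
  innov <- with_seed(seed, matrix(stats::rnorm(d * total, sd = model$noise_sd),
                                  d, total))
  for (t in seq_len(total)) {
    xt <- innov[, t]
    for (k in seq_len(p)) xt <- xt + model$transition[[k]] %*% X[, t + p - k]
    X[, t + p] <- xt
  }
  X[, (p + burn_in + 1):(p + total), drop = FALSE]
}

#' Simulation scenario
#'
#' One Monte-Carlo condition of the benchmark. `kind = "patch"` is the
#' extended-source localization experiment (one random patch per trial,
#' smooth waveform); `kind = "causal"` is the time-series recovery
#' experiment (two non-overlapping patches driven by a stationary vector
#' autoregression, sensor noise, then zero-phase band-pass).
#'
#' @param kind `"patch"` or `"causal"`.
#' @param ln_level neighborhood level 1..3 (patch extent).
#' @param snr_db sensor SNR in dB.
#' @param n_trials Monte-Carlo trials (benchmark default 200).
#' @param seed scenario seed; per-trial seeds are derived from it.
#' @param T samples per trial. @param fs sampling rate, Hz.
#' @param waveform waveform kind for patch trials.
#' @param ar list of AR settings for causal trials
#'   (`order`, `n_active`, `spectral_radius`, `noise_sd`).
#' @param filter band-pass settings for causal trials
#'   (`low`, `high`, `order`), or NULL to skip filtering.
#' @param ring_amplitudes relative ring amplitudes.
#' @return a `simulation_scenario`.
#' @export
simulation_scenario <- function(kind = c("patch", "causal"), ln_level = 1L,
                                snr_db = 40, n_trials = 200L, seed = 1L,
                                T = if (match.arg(kind) == "patch") 100L else 500L,
                                fs = 100,
                                waveform = "gauss_sine",
                                ar = list(order = 1L, n_active = 2L,
                                          spectral_radius = 0.9, noise_sd = 1),
                                filter = list(low = 0.1, high = 40, order = 3L),
                                ring_amplitudes = c(0.8, 0.6, 0.4)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, ln_level = as.integer(ln_level),
                 snr_db = snr_db, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), T = as.integer(T), fs = fs,
                 waveform = waveform, ar = ar, filter = filter,
                 ring_amplitudes = ring_amplitudes),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("<simulation_scenario> ", x$kind, ": LN = ", x$ln_level, ", SNR = ",
      x$snr_db, " dB, ", x$n_trials, " trials, T = ", x$T, "\n", sep = "")
  invisible(x)
}

#' Generate one simulated trial
#'
#' For patch scenarios: a random center vertex, ring-decayed patch
#' amplitudes, `S_true = amplitudes %o% waveform`, `Y = K S_true` plus
#' sensor noise at the scenario SNR. For causal scenarios: two random
#' non-overlapping patches whose vertices share the patch's AR time course
#' scaled by the ring amplitude; noise is added to the sensor signal and
#' the zero-phase band-pass is applied last, following the stated
#' generation order (noise, then filter).
#'
#' @param scenario a `simulation_scenario`.
#' @param graph the `source_space_graph`.
#' @param forward the `forward_model` (leadfield over the same sources).
#' @param trial trial index (1-based); combined with the scenario seed to
#'   derive the per-trial seed.
#' @return list with `measurement` and `truth` (the latter carries
#'   `S_true`; for causal trials also `centers`, `patches` and the raw AR
#'   `courses`).
#' @export
build_trial <- function(scenario, graph, forward, trial = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            inherits(graph, "source_space_graph"),
            inherits(forward, "forward_model"))
  K <- forward$leadfield
  if (ncol(K) != graph$n_nodes)
    stop("leadfield sources and graph nodes differ")
  tseed <- (scenario$seed * 10007L + trial * 7919L) %% 2147483647L
  if (scenario$kind == "patch") {
    center <- with_seed(tseed, sample.int(graph$n_nodes, 1L))
    truth <- sample_patch(graph, center, scenario$ln_level,
                          scenario$ring_amplitudes)
    w <- make_waveform(scenario$waveform, scenario$T, scenario$fs,
                       seed = tseed + 1L)
    truth$S_true <- outer(truth$amplitudes, w)
    Y <- add_sensor_noise(K %*% truth$S_true, scenario$snr_db,
                          seed = tseed + 2L, fs = scenario$fs)
    return(list(measurement = Y, truth = truth))
  }

  ## causal scenario: two non-overlapping patches with AR courses
  n_active <- scenario$ar$n_active
  sel <- with_seed(tseed, {
    repeat {
      centers <- sample.int(graph$n_nodes, n_active)
      patches <- lapply(centers, sample_patch, graph = graph,
                        ln_level = scenario$ln_level,
                        ring_amplitudes = scenario$ring_amplitudes)
      overlap <- length(Reduce(intersect,
                               lapply(patches, `[[`, "active_set"))) > 0
      if (!overlap || n_active == 1L) break
    }
    list(centers = centers, patches = patches)
  })
  arm <- rand_ar_model(n_active, scenario$ar$order,
                       scenario$ar$spectral_radius,
                       scenario$ar$noise_sd %||% 1, seed = tseed + 3L)
  courses <- gen_ar_sources(arm, scenario$T, seed = tseed + 4L)
  ## the simulated brain signal lives in the analysis band: a raw AR draw
  ## can oscillate near Nyquist, which no band-limited measurement could
  ## ever represent, so the source courses are band-limited with the same
  ## zero-phase filter that is later applied to the sensor data
  if (!is.null(scenario$filter))
    courses <- bandpass_zero_phase(courses, scenario$fs, scenario$filter$low,
                                   scenario$filter$high, scenario$filter$order)
  S_true <- matrix(0, graph$n_nodes, scenario$T)
  for (j in seq_len(n_active)) {
    pj <- sel$patches[[j]]
    S_true[pj$active_set, ] <- S_true[pj$active_set, , drop = FALSE] +
      outer(pj$amplitudes[pj$active_set], courses[j, ])
  }
  active <- which(rowSums(abs(S_true)) > 0)
  Y <- add_sensor_noise(K %*% S_true, scenario$snr_db, seed = tseed + 5L,
                        fs = scenario$fs)
  if (!is.null(scenario$filter))
    Y$data <- bandpass_zero_phase(Y$data, scenario$fs, scenario$filter$low,
                                  scenario$filter$high, scenario$filter$order)
  truth <- structure(list(amplitudes = as.numeric(rowSums(abs(S_true)) > 0),
                          active_set = active,
                          center_index = sel$centers[1],
                          centers = sel$centers,
                          patches = sel$patches,
                          courses = courses,
                          ar_model = arm,
                          ln_level = scenario$ln_level,
                          S_true = S_true),
                     class = "ground_truth")
  list(measurement = Y, truth = truth)
}
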