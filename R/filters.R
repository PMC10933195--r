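#' Butterworth band-pass filter design
#'
#' Digital Butterworth band-pass via the standard analog-prototype route:
#' analog low-pass poles on the unit circle, low-pass to band-pass
#' transformation around the pre-warped band edges, then the bilinear
#' transform. Matches the coefficients produced by the reference scientific
#' stacks to machine precision.
#'
#' @param order filter order of the low-pass prototype (the band-pass has
#'   2*order poles).
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(order = 3L, low = 0.1, high = 40, fs = 100) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist)")
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)      # pre-warped analog edges
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  ## analog low-pass prototype (poles only, unit gain)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  ## low-pass -> band-pass (each pole splits in two; `order` zeros at 0)
  p_sc <- p_lp * bw / 2
  p_bp <- c(p_sc + sqrt(p_sc^2 - w0^2), p_sc - sqrt(p_sc^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  k_bp <- bw^order

  ## bilinear transform
  z_d <- (fs2 + z_bp) / (fs2 - z_bp)
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  k_d <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))

  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a)
}

## monic polynomial coefficients from complex roots
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (x in r) cf <- c(cf, 0) - c(0, cf * x)
  cf
}

## IIR filter (direct form II transposed), rows of X filtered independently.
## zi: per-channel initial state, n_channels x (n-1).
iir_filter <- function(b, a, X, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  one_row <- is.null(dim(X))
  if (one_row) X <- matrix(X, 1)
  C <- nrow(X); T_ <- ncol(X)
  z <- if (is.null(zi)) matrix(0, C, n - 1) else matrix(zi, C, n - 1)
  Y <- matrix(0, C, T_)
  for (t in seq_len(T_)) {
    xt <- X[, t]
    yt <- b[1] * xt + z[, 1]
    if (n > 2)
      z[, 1:(n - 2)] <- z[, 2:(n - 1), drop = FALSE] +
        outer(xt, b[2:(n - 1)]) - outer(yt, a[2:(n - 1)])
    z[, n - 1] <- b[n] * xt - a[n] * yt
    Y[, t] <- yt
  }
  if (one_row) drop(Y) else Y
}

## steady-state initial filter state for a unit-step input
iir_filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  comp_t <- rbind(-a[2:n], cbind(diag(1, n - 2), 0))  # companion matrix of a
  IminusA <- diag(n - 1) - t(comp_t)
  B <- b[2:n] - a[2:n] * b[1]
  solve(IminusA, B)
}

#' Zero-phase band-pass filtering
#'
#' Forward-backward application of a Butterworth band-pass so the net phase
#' delay is zero. The signal is extended at both ends by odd reflection
#' (default length 3 * (number of taps)) and the filter state is initialized
#' at its constant-input steady state, which suppresses startup transients.
#'
#' @param x numeric vector, or matrix with one signal per row.
#' @param fs sampling rate, Hz.
#' @param low,high pass-band edges, Hz (defaults 0.1 and 40).
#' @param order Butterworth order (default 3).
#' @param padlen reflection padding length.
#' @return filtered signal with the same shape as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, low = 0.1, high = 40, order = 3L,
                                padlen = NULL) {
  ba <- butter_bandpass(order, low, high, fs)
  filtfilt_ba(ba$b, ba$a, x, padlen)
}

filtfilt_ba <- function(b, a, x, padlen = NULL) {
  one_row <- is.null(dim(x))
  X <- if (one_row) matrix(x, 1) else as.matrix(x)
  T_ <- ncol(X)
  n <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3L * n
  if (padlen >= T_)
    stop("signal too short for zero-phase filtering: need length > ", padlen)
  ## odd reflection about the end points
  left <- 2 * X[, 1] - X[, (padlen + 1):2, drop = FALSE]
  right <- 2 * X[, T_] - X[, (T_ - 1):(T_ - padlen), drop = FALSE]
  E <- cbind(left, X, right)
  zi <- iir_filter_zi(b, a)
  Y <- iir_filter(b, a, E, zi = outer(E[, 1], zi))
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y <- iir_filter(b, a, Y, zi = outer(Y[, 1], zi))
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y <- Y[, (padlen + 1):(padlen + T_), drop = FALSE]
  if (one_row) drop(Y) else Y
}
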