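#' @keywords internal
new_source_estimate <- function(data, method, variant = "original",
                                lam = NA_real_, basis_P = NULL,
                                convergence = NULL) {
  structure(list(data = data, method = method, variant = variant,
                 lam = lam, basis_P = basis_P, convergence = convergence),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat("<source_estimate> ", nrow(x$data), " sources x ", ncol(x$data),
      " time points | ", if (x$variant == "gft") "GFT-" else "", x$method,
      ", lambda = ", format(x$lam),
      if (!is.null(x$basis_P)) paste0(", P = ", x$basis_P), "\n", sep = "")
  if (!is.null(x$convergence) && !isTRUE(x$convergence$converged))
    cat("  (solver stopped at max_iter without reaching tol)\n")
  invisible(x)
}

as_data_matrix <- function(Y) {
  if (inherits(Y, "measurement")) Y <- Y$data
  as.matrix(Y)
}

## Economy SVD of the leadfield with rank detection, shared by the
## standardized solvers. Components with s <= rtol * s_max are treated as
## exact zeros (they carry no measurable signal).
lead_svd <- function(K, rtol = 1e-10) {
  sv <- svd(K)
  keep <- sv$d > rtol * sv$d[1]
  list(u = sv$u[, keep, drop = FALSE], d = sv$d[keep],
       v = sv$v[, keep, drop = FALSE])
}

#' Minimum norm estimate (MNE)
#'
#' L2-regularized inverse solution
#' \eqn{\hat S = K^T (K K^T + \lambda I)^{-1} Y}, computed through a
#' symmetric (Cholesky) solve, never an explicit inverse.
#'
#' @param K leadfield, C x N.
#' @param Y measurements, C x T (a plain matrix or a `measurement`).
#' @param lam regularization \eqn{\lambda \ge 0}; 0 is only valid when
#'   `K K^T` is invertible.
#' @return a `source_estimate` (N x T).
#' @export
mne_solve <- function(K, Y, lam) {
  Y <- as_data_matrix(Y)
  stopifnot(lam >= 0)
  G <- tcrossprod(K) + diag(lam, nrow(K))
  R <- tryCatch(chol(G), error = function(e)
    stop("K K^T + lambda I is singular; set lam > 0 (got lam = ", lam, ")"))
  S <- crossprod(K, backsolve(R, forwardsolve(t(R), Y)))
  new_source_estimate(S, "mne", lam = lam)
}

#' sLORETA standardized inverse solution
#'
#' Minimum-norm estimate standardized by the inverse square root of the
#' resolution matrix \eqn{R = K^T (K K^T + \lambda I)^{-1} K}:
#' \eqn{\hat S = R^{-1/2} K^T (K K^T + \lambda I)^{-1} Y}.
#'
#' With `standardization = "matrix"` the full-matrix \eqn{-1/2} power is
#' used as printed, evaluated on the signal subspace through the SVD of K
#' (for singular values s this collapses to the exact diagonal form
#' \eqn{1/\sqrt{s^2+\lambda}} in the right-singular basis, which avoids
#' amplifying rounding noise in the numerical null space). With
#' `"diagonal"` only the diagonal of R standardizes each source, the
#' convention many ecosystem implementations use.
#'
#' @inheritParams mne_solve
#' @param standardization `"matrix"` (as printed) or `"diagonal"`.
#' @export
sloreta_solve <- function(K, Y, lam, standardization = c("matrix", "diagonal")) {
  standardization <- match.arg(standardization)
  Y <- as_data_matrix(Y)
  stopifnot(lam > 0)
  sv <- lead_svd(K)
  UtY <- crossprod(sv$u, Y)
  if (standardization == "matrix") {
    S <- sv$v %*% (UtY / sqrt(sv$d^2 + lam))
  } else {
    w <- sv$d / (sv$d^2 + lam)
    rho <- sv$d^2 / (sv$d^2 + lam)
    dR <- drop(sv$v^2 %*% rho)               # diag of the resolution matrix
    scale <- ifelse(dR > 1e-12 * max(dR), 1 / sqrt(dR), 0)
    S <- scale * (sv$v %*% (w * UtY))
  }
  new_source_estimate(S, "sloreta", lam = lam)
}

#' dSPM standardized inverse solution
#'
#' With \eqn{M = K^T (K K^T + \lambda I)^{-1}} and identity noise
#' covariance, \eqn{\hat S = (M M^T)^{-1/2} M Y}. The full-matrix form is
#' evaluated on the signal subspace via the SVD of K; the diagonal form
#' divides each source by the root of its row of \eqn{M M^T}.
#'
#' @inheritParams sloreta_solve
#' @export
dspm_solve <- function(K, Y, lam, standardization = c("matrix", "diagonal")) {
  standardization <- match.arg(standardization)
  Y <- as_data_matrix(Y)
  stopifnot(lam > 0)
  sv <- lead_svd(K)
  UtY <- crossprod(sv$u, Y)
  if (standardization == "matrix") {
    ## (M M^T)^{-1/2} M = V diag(1/w) V^T V diag(w) U^T = V U^T on the
    ## signal subspace
    S <- sv$v %*% UtY
  } else {
    w <- sv$d / (sv$d^2 + lam)
    dM <- drop(sv$v^2 %*% w^2)               # diag of M M^T
    scale <- ifelse(dM > 1e-24 * max(dM), 1 / sqrt(dM), 0)
    S <- scale * (sv$v %*% (w * UtY))
  }
  new_source_estimate(S, "dspm", lam = lam)
}

## proximal operators
prox_l1 <- function(X, thr) sign(X) * pmax(abs(X) - thr, 0)
prox_l21 <- function(X, thr) {
  rn <- sqrt(rowSums(X^2))
  X * ifelse(rn > 0, pmax(0, 1 - thr / rn), 0)
}

## FISTA with adaptive restart and monotone (MFISTA) safeguard.
## penalty(S) returns lam * R(S); prox(X, t) is the proximal map of t*R.
fista <- function(K, Y, lam, prox, penalty, tol = 1e-6, max_iter = 1000L) {
  N <- ncol(K); T_ <- ncol(Y)
  KtY <- crossprod(K, Y)
  Lip <- power_iteration_sq_norm(K)
  step <- 1 / Lip
  obj <- function(S) {
    R <- Y - K %*% S
    0.5 * sum(R^2) + penalty(S)
  }
  S <- matrix(0, N, T_)
  Z <- S
  t_k <- 1
  f_S <- obj(S)
  objectives <- numeric(max_iter)
  stall <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- crossprod(K, K %*% Z) - KtY
    S_cand <- prox(Z - step * grad, lam * step)
    f_cand <- obj(S_cand)
    if (f_cand > f_S) {            # monotone safeguard + restart
      S_new <- S; f_new <- f_S
      Z <- S_cand
      t_k <- 1
    } else {
      t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
      Z <- S_cand + ((t_k - 1) / t_next) * (S_cand - S)
      t_k <- t_next
      S_new <- S_cand; f_new <- f_cand
    }
    objectives[it] <- f_new
    ## relative objective decrease; the scale is the objective itself, not
    ## an absolute unit (leadfield units are arbitrary)
    if (abs(f_S - f_new) <= tol * max(abs(f_new), .Machine$double.xmin)) {
      stall <- stall + 1L
      if (stall >= 3L) { S <- S_new; f_S <- f_new; converged <- TRUE; break }
    } else stall <- 0L
    S <- S_new; f_S <- f_new
  }
  list(S = S, objective = f_S, objectives = objectives[seq_len(it)],
       iterations = it, converged = converged)
}

## squared spectral norm of K by power iteration on K^T K
power_iteration_sq_norm <- function(K, iters = 60L, tol = 1e-10) {
  v <- rep(1 / sqrt(ncol(K)), ncol(K))
  lam_old <- 0
  for (i in seq_len(iters)) {
    w <- crossprod(K, K %*% v)
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(.Machine$double.eps)
    v <- w / lam
    if (abs(lam - lam_old) <= tol * lam) break
    lam_old <- lam
  }
  lam * 1.01            # slight inflation keeps the step strictly valid
}

#' Minimum current estimate (MCE, L1)
#'
#' Solves \eqn{\hat S = \arg\min_S \frac12 \|Y - K S\|_F^2 + \lambda
#' \|S\|_1} with FISTA (step \eqn{1/\|K\|_2^2}, adaptive restart, monotone
#' safeguard). If `max_iter` is reached before the tolerance, the estimate
#' carries `convergence$converged = FALSE` rather than an error.
#'
#' @inheritParams mne_solve
#' @param lam regularization \eqn{\lambda > 0}.
#' @param tol relative objective-decrease stopping tolerance.
#' @param max_iter iteration cap.
#' @export
mce_solve <- function(K, Y, lam, tol = 1e-6, max_iter = 1000L) {
  Y <- as_data_matrix(Y)
  stopifnot(lam > 0)
  fit <- fista(K, Y, lam, prox_l1, function(S) lam * sum(abs(S)),
               tol = tol, max_iter = max_iter)
  new_source_estimate(fit$S, "mce", lam = lam,
                      convergence = fit[c("objective", "iterations", "converged")])
}

#' Mixed-norm estimate (MxNE, L2,1)
#'
#' Solves \eqn{\hat S = \arg\min_S \frac12 \|Y - K S\|_F^2 + \lambda
#' \|S\|_{2,1}} where the penalty is the sum of the L2 norms of the rows
#' (L2 across time, L1 across sources), by FISTA with a row-wise group
#' soft-threshold. For T = 1 this reduces exactly to [mce_solve()].
#'
#' @inheritParams mce_solve
#' @export
mxne_l21_solve <- function(K, Y, lam, tol = 1e-6, max_iter = 1000L) {
  Y <- as_data_matrix(Y)
  stopifnot(lam > 0, ncol(Y) >= 1)
  fit <- fista(K, Y, lam, prox_l21,
               function(S) lam * sum(sqrt(rowSums(S^2))),
               tol = tol, max_iter = max_iter)
  new_source_estimate(fit$S, "l21", lam = lam,
                      convergence = fit[c("objective", "iterations", "converged")])
}

#' Largest useful sparse-penalty weight
#'
#' The smallest \eqn{\lambda} for which the all-zero matrix solves the
#' L1 (resp. L2,1) problem: \eqn{\|K^T Y\|_\infty} elementwise, or the
#' largest row norm of \eqn{K^T Y}.
#'
#' @inheritParams mne_solve
#' @param penalty `"l1"` or `"l21"`.
#' @export
lambda_max <- function(K, Y, penalty = c("l1", "l21")) {
  penalty <- match.arg(penalty)
  KtY <- crossprod(K, as_data_matrix(Y))
  if (penalty == "l1") max(abs(KtY)) else max(sqrt(rowSums(KtY^2)))
}

#' Default regularization for the closed-form solvers
#'
#' Classical minimum-norm heuristic
#' \eqn{\lambda = \mathrm{tr}(K K^T) / (C \cdot \mathrm{SNR})} with SNR on
#' the linear (power-ratio) scale.
#'
#' @param K leadfield. @param snr_db signal-to-noise ratio in dB.
#' @export
default_lambda <- function(K, snr_db) {
  sum(K^2) / (nrow(K) * 10^(snr_db / 10))
}

#' Solve the inverse problem in the GFT-projected subspace
#'
#' Forms the reduced leadfield \eqn{\tilde K = K \tilde U}, runs the named
#' solver on \eqn{(\tilde K, Y)} to obtain the reduced estimate
#' \eqn{\tilde S^*} (P x T), and back-projects through the inverse GFT
#' \eqn{\hat S_{GFT} = \tilde U \tilde S^*}. For sLORETA/dSPM the
#' standardization matrices are computed in the reduced space and then
#' back-projected, as in their projected closed forms.
#'
#' @param method one of `"mne"`, `"sloreta"`, `"dspm"`, `"mce"`, `"l21"`.
#' @inheritParams mne_solve
#' @param low_basis N x P matrix with orthonormal columns (from
#'   [select_low_band()]).
#' @param ... further arguments for the underlying solver
#'   (`standardization`, `tol`, `max_iter`).
#' @return a `source_estimate` (N x T) with `variant = "gft"` and
#'   `basis_P = P`; the estimate lies in the span of `low_basis`.
#' @export
gft_solve <- function(method = c("mne", "sloreta", "dspm", "mce", "l21"),
                      K, Y, low_basis, lam, ...) {
  method <- match.arg(method)
  Y <- as_data_matrix(Y)
  U_low <- as.matrix(low_basis)
  if (ncol(U_low) > nrow(U_low)) stop("low_basis must be N x P with P <= N")
  Kt <- K %*% U_low
  solver <- switch(method, mne = mne_solve, sloreta = sloreta_solve,
                   dspm = dspm_solve, mce = mce_solve, l21 = mxne_l21_solve)
  red <- solver(Kt, Y, lam, ...)
  est <- new_source_estimate(U_low %*% red$data, method, variant = "gft",
                             lam = lam, basis_P = ncol(U_low),
                             convergence = red$convergence)
  est
}
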