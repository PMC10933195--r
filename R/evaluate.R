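source_power <- function(estimate) {
  S <- if (inherits(estimate, "source_estimate")) estimate$data else as.matrix(estimate)
  rowSums(S^2)
}

#' Localization error
#'
#' Euclidean distance (mm) between the true patch center and the estimated
#' center. The estimated center is the vertex with maximal time-integrated
#' power (`center = "argmax"`, default) or the energy-weighted centroid
#' projected to the nearest vertex (`center = "centroid"`).
#'
#' @param estimate a `source_estimate` (or N x T matrix).
#' @param truth a `ground_truth`.
#' @param coords N x 3 vertex coordinates, mm.
#' @param center `"argmax"` or `"centroid"`.
#' @return distance in mm. An all-zero estimate has no meaningful argmax:
#'   the maximal distance from the true center to any vertex is returned
#'   with attribute `flagged = TRUE` and a warning.
#' @export
localization_error <- function(estimate, truth, coords,
                               center = c("argmax", "centroid")) {
  center <- match.arg(center)
  pw <- source_power(estimate)
  true_xyz <- coords[truth$center_index, ]
  if (all(pw == 0)) {
    warning("all-zero estimate: returning maximal-distance sentinel")
    d <- max(sqrt(colSums((t(coords) - true_xyz)^2)))
    return(structure(d, flagged = TRUE))
  }
  est_xyz <- if (center == "argmax") {
    coords[which.max(pw), ]
  } else {
    cen <- colSums(coords * pw) / sum(pw)
    coords[which.min(colSums((t(coords) - cen)^2)), ]
  }
  sqrt(sum((est_xyz - true_xyz)^2))
}

#' ROC area for source-extent recovery
#'
#' Scores each source by its time-integrated energy and computes the area
#' under the ROC curve against binary membership in the true active set,
#' using the rank (Mann-Whitney) statistic with ties averaged. 1 means the
#' whole active patch outranks every inactive source; 0.5 is chance.
#'
#' @inheritParams localization_error
#' @return AUC in `[0, 1]`.
#' @export
auc_extent <- function(estimate, truth) {
  pw <- source_power(estimate)
  labels <- seq_along(pw) %in% truth$active_set
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("degenerate labels: active set must be nonempty and not all sources")
  r <- rank(pw)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Time-course correlation
#'
#' Pearson correlation between the true time course of each activated
#' patch and the estimated course at that patch, where the estimated
#' course is the energy-weighted average of the estimate rows over the
#' patch's true active set. With several patches the mean over patches is
#' returned; polarity is not rectified, so a solver that flips sign is
#' penalized.
#'
#' @inheritParams localization_error
#' @return mean Pearson correlation in `[-1, 1]`.
#' @export
timecourse_correlation <- function(estimate, truth) {
  S <- if (inherits(estimate, "source_estimate")) estimate$data else as.matrix(estimate)
  if (ncol(S) < 3) stop("need T >= 3 time points for a correlation")
  patches <- if (!is.null(truth$patches)) {
    lapply(seq_along(truth$patches), function(j)
      list(idx = truth$patches[[j]]$active_set,
           course = truth$courses[j, ]))
  } else {
    list(list(idx = truth$active_set,
              course = truth$S_true[truth$center_index, ]))
  }
  cors <- vapply(patches, function(p) {
    sub <- S[p$idx, , drop = FALSE]
    w <- rowSums(sub^2)
    if (sum(w) == 0) stop("zero-variance estimated course: correlation undefined")
    est_course <- colSums(sub * w) / sum(w)
    if (stats::sd(est_course) == 0 || stats::sd(p$course) == 0)
      stop("zero-variance series: correlation undefined")
    stats::cor(est_course, p$course)
  }, numeric(1))
  mean(cors)
}

#' Paired t test with the benchmark's star convention
#'
#' Classical paired two-sided t test. Stars follow the printed thresholds
#' `* p < 0.5`, `** p < 0.05`, `*** p < 0.005` (the 0.5 threshold is
#' reproduced as printed; see the package vignette). Degenerate cases:
#' identical vectors give t = 0 and p = 1; a constant nonzero difference
#' gives an infinite t, p = 0 and three stars.
#'
#' @param scores_a,scores_b equal-length numeric vectors paired by trial.
#' @return list with `t`, `p`, `stars`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("paired vectors must have equal length")
  n <- length(scores_a)
  if (n < 2) stop("need at least 2 pairs")
  d <- scores_a - scores_b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, stars = ""))
    return(list(t = sign(mean(d)) * Inf, p = 0, stars = "***"))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  stars <- if (p < 0.005) "***" else if (p < 0.05) "**" else if (p < 0.5) "*" else ""
  list(t = t_stat, p = p, stars = stars)
}
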