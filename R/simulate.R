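#' Simulate calibrated predictions from an ensemble of binary classifiers
#'
#' Draws class-conditioned Gaussian scores for M base classifiers over N
#' samples and rank-transforms them. The negative class has mean zero and the
#' positive class mean of classifier i is set from its target AUC through
#' \eqn{\mu_i = \sqrt{2}\,\Phi^{-1}(AUC_i)} (unit variances in both classes).
#' Both classes share `conditional_corr` as their covariance matrix, so the
#' identity matrix produces class-conditionally independent classifiers —
#' the regime in which the unsupervised estimator is exact. Class sizes are
#' deterministic: `N1 = round(prevalence * N)` positive samples.
#'
#' Higher scores indicate positive-leaning predictions, so the returned rank
#' matrix (via [rank_transform()]) follows the rank-1-is-most-positive
#' convention. With a seed the output is bit-reproducible; the caller's RNG
#' state is left untouched.
#'
#' @param aucs length-M vector of target AUCs in (0, 1).
#' @param prevalence positive-class prevalence \eqn{\rho \in (0,1)};
#'   `round(rho*N)` and `round((1-rho)*N)` must both be at least 2.
#' @param n_samples number of samples N.
#' @param conditional_corr M x M class-conditioned correlation matrix
#'   (default identity: conditional independence).
#' @param seed optional integer seed.
#' @return list with `scores` (M x N), `ranks` (M x N), `labels` (length-N
#'   0/1 vector; positives first), and the generating parameters in
#'   `prevalence` and `aucs`.
#' @examples
#' sim <- simulate_predictions(c(0.6, 0.7, 0.8), 0.3, 100, seed = 1)
#' rowSums(sim$ranks)  # each 100*101/2
#' @export
simulate_predictions <- function(aucs, prevalence, n_samples,
                                 conditional_corr = diag(length(aucs)),
                                 seed = NULL) {
  m <- length(aucs)
  if (any(aucs <= 0) || any(aucs >= 1)) stop("`aucs` must lie strictly inside (0, 1)")
  n1 <- round(prevalence * n_samples)
  n0 <- n_samples - n1
  if (n1 < 2 || n0 < 2) stop("each class needs at least 2 samples: adjust prevalence or N")
  conditional_corr <- as_spsd(conditional_corr, m)
  if (max(abs(diag(conditional_corr) - 1)) > 1e-8) {
    stop("`conditional_corr` must have unit diagonal")
  }
  ev <- eigen(conditional_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop(sprintf("`conditional_corr` is not positive semi-definite (eigenvalue %.3g)",
                 min(ev$values)))
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  z <- matrix(stats::rnorm(m * n_samples), nrow = m)
  scores <- L %*% z
  mu <- sqrt(2) * stats::qnorm(aucs)      # positive-class mean per classifier
  labels <- c(rep(1L, n1), rep(0L, n0))
  scores[, labels == 1L] <- scores[, labels == 1L] + mu
  rownames(scores) <- paste0("clf", seq_len(m))
  colnames(scores) <- paste0("s", seq_len(n_samples))
  names(labels) <- colnames(scores)
  list(scores = scores, ranks = rank_transform(scores), labels = labels,
       prevalence = prevalence, aucs = aucs)
}

#' Random conditional-dependence matrix
#'
#' Generates a valid correlation matrix whose off-diagonal magnitudes grow
#' with `strength`, from a seeded random two-factor model projected to unit
#' diagonal. `strength = 0` returns the identity. This emulates the
#' heterogeneous dependence structure of real challenge submissions with a
#' single dial; it is a synthetic stand-in, not a reproduction of any
#' particular dataset.
#'
#' @param m number of classifiers M.
#' @param strength dependence dial in `[0, 1)`.
#' @param seed optional integer seed (caller's RNG state preserved).
#' @return M x M correlation matrix (symmetric PSD, unit diagonal).
#' @export
sample_dependence_matrix <- function(m, strength, seed = NULL) {
  if (strength < 0 || strength >= 1) stop("`strength` must lie in [0, 1)")
  if (strength == 0) return(diag(m))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  f <- matrix(stats::rnorm(m * 2L), nrow = m)          # random loadings, 2 factors
  S <- strength * tcrossprod(f) + (1 - strength) * diag(m) * rowSums(f^2)
  d <- sqrt(diag(strength * tcrossprod(f)) + (1 - strength) * rowSums(f^2))
  R <- S / tcrossprod(d)
  diag(R) <- 1
  (R + t(R)) / 2
}
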