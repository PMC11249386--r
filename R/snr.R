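#' Signal-to-noise ratio of a single classifier
#'
#' The SNR of a rank-calibrated classifier is the difference between the
#' negative- and positive-class mean ranks, divided by the square root of the
#' summed class-conditioned rank variances,
#' \deqn{S = \frac{\mu_{|0} - \mu_{|1}}{\sqrt{\sigma^2_{|1} + \sigma^2_{|0}}}.}
#' Variances are population-normalized (divide by the class count, not
#' count - 1); under that convention the closed form of [max_snr()] is exact
#' for finite N. Under the rank-1-is-most-positive convention a
#' better-than-random classifier has positive SNR; a negative SNR flags a
#' classifier ranked against the convention.
#'
#' @param ranks_row numeric vector of within-classifier sample ranks.
#' @param labels 0/1 vector of the same length, 1 = positive class.
#' @return the SNR (a unitless scalar).
#' @examples
#' classifier_snr(c(1, 2, 3, 4), c(1, 1, 0, 0))  # 2*sqrt(2), a perfect ranking
#' @export
classifier_snr <- function(ranks_row, labels) {
  labels <- as_labels(labels, n = length(ranks_row))
  r1 <- ranks_row[labels == 1L]
  r0 <- ranks_row[labels == 0L]
  v1 <- pop_var(r1)
  v0 <- pop_var(r0)
  if (v1 + v0 <= 0) {
    stop("degenerate input: both class-conditioned rank variances are zero")
  }
  (mean(r0) - mean(r1)) / sqrt(v1 + v0)
}

pop_var <- function(x) mean((x - mean(x))^2)

#' SNR of a weighted linear ensemble
#'
#' For ensemble score \eqn{s_k = \sum_i w_i r_{ik}}, the ensemble SNR is
#' \deqn{S_{ens}(w) = \frac{w^\top \Delta}{\sqrt{w^\top C w}},}
#' where \eqn{\Delta} is the vector of class-conditioned mean-rank differences
#' and \eqn{C = C_0 + C_1} is the sum of the class-conditioned covariance
#' matrices. The value is invariant to positive rescaling of `w`.
#'
#' @param w numeric weight vector, length M.
#' @param delta numeric vector \eqn{\Delta}, length M.
#' @param C symmetric positive semi-definite M x M matrix \eqn{C_0 + C_1}.
#' @return the ensemble SNR.
#' @seealso [optimal_ensemble_snr()] for the maximum over `w`,
#'   [moca_weights()] for the maximizing weights.
#' @export
ensemble_snr <- function(w, delta, C) {
  C <- as_spsd(C, length(w))
  if (length(delta) != length(w)) stop("`w` and `delta` lengths differ")
  q <- drop(crossprod(w, C %*% w))
  if (q <= 0) stop("w'Cw must be positive (C not PSD, or w in its null space)")
  drop(crossprod(w, delta)) / sqrt(q)
}

#' Maximum ensemble SNR over all linear weights
#'
#' The SNR attained by the optimal weights \eqn{w \propto C^{-1}\Delta},
#' \deqn{S_{ens}^{max} = \|C^{-1/2}\Delta\| = \sqrt{\Delta^\top C^{-1} \Delta}.}
#' With diagonal C (class-conditionally independent classifiers) this reduces
#' to \eqn{\sqrt{\sum_i \Delta_i^2 / (\sigma^2_{i|1} + \sigma^2_{i|0})}}, so
#' for M independent classifiers of equal individual SNR the ensemble SNR
#' grows as \eqn{\sqrt{M}}.
#'
#' @param delta numeric vector \eqn{\Delta}, length M.
#' @param C symmetric positive definite M x M matrix.
#' @return the optimal ensemble SNR (a nonnegative scalar).
#' @export
optimal_ensemble_snr <- function(delta, C) {
  C <- as_spsd(C, length(delta))
  x <- tryCatch(solve(C, delta),
                error = function(e) stop("C is singular; regularize (ridge) or drop duplicated classifiers"))
  sqrt(max(0, drop(crossprod(delta, x))))
}

as_spsd <- function(C, m) {
  C <- as.matrix(C)
  if (nrow(C) != m || ncol(C) != m) stop("C has wrong dimensions")
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) stop("C must be symmetric")
  (C + t(C)) / 2
}

#' Maximum attainable SNR of a perfect classifier
#'
#' A classifier with AUC = 1 ranks every positive sample ahead of every
#' negative one; its rank distribution is uniform over `1..N1` given the
#' positive class and over `N1+1..N` given the negative class. The resulting
#' SNR has the closed form
#' \deqn{SNR(\rho, N; AUC = 1) = \sqrt{3} \big/ \sqrt{(1-\rho)^2 + \rho^2 - 2/N^2},}
#' which is bounded above by \eqn{\sqrt{6}/\sqrt{1 - 4/N^2}} (attained at
#' prevalence 1/2). It is an analytic ceiling against which single-classifier
#' and ensemble SNRs can be compared.
#'
#' @param prevalence positive-class prevalence \eqn{\rho \in (0,1)}.
#' @param n_samples number of samples N (>= 2). `round(prevalence * n_samples)`
#'   must leave at least one sample in each class.
#' @return the maximum SNR.
#' @examples
#' max_snr(0.4, 200)  # about 2.40
#' @export
max_snr <- function(prevalence, n_samples) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly inside (0, 1)")
  }
  if (!is.numeric(n_samples) || n_samples < 2) stop("`n_samples` must be >= 2")
  n1 <- round(prevalence * n_samples)
  if (n1 < 1 || n_samples - n1 < 1) {
    stop("prevalence and n_samples must leave at least one sample in each class")
  }
  sqrt(3) / sqrt((1 - prevalence)^2 + prevalence^2 - 2 / n_samples^2)
}

#' Convert between SNR and AUC for Gaussian class-conditioned scores
#'
#' For normally distributed class-conditioned scores the AUC is
#' \eqn{\Phi(S/\sqrt{2})} where \eqn{\Phi} is the standard normal CDF;
#' `auc_to_snr()` is the exact inverse. The relation is the sigmoidal link
#' between the two performance scales: SNR 0 is AUC 0.5, and negating the SNR
#' reflects the AUC about 0.5.
#'
#' @param s an SNR value.
#' @return `snr_to_auc`: the AUC in (0, 1).
#' @export
snr_to_auc <- function(s) stats::pnorm(s / sqrt(2))

#' @rdname snr_to_auc
#' @param auc an AUC strictly inside (0, 1); the endpoints map to infinite SNR
#'   and are rejected.
#' @return `auc_to_snr`: the SNR.
#' @export
auc_to_snr <- function(auc) {
  if (any(auc <= 0) || any(auc >= 1)) {
    stop("`auc` must lie strictly inside (0, 1): AUC of 0 or 1 has infinite SNR")
  }
  sqrt(2) * stats::qnorm(auc)
}
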