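#' Class-conditioned rank moments
#'
#' Computes, for each base classifier, the class-conditioned mean ranks and
#' the class-conditioned covariance matrices of the rank rows, using
#' population normalization (divide by the class count). These are the
#' sufficient statistics of the supervised weight estimator:
#' \eqn{\Delta_i = \mu_{i|0} - \mu_{i|1}} and \eqn{C = C_0 + C_1}.
#'
#' @param ranks M x N rank matrix (see [rank_transform()]).
#' @param labels 0/1 vector of length N.
#' @return an object of class `"moca_moments"`: a list with elements `mu0`,
#'   `mu1`, `delta` (length-M vectors), `C0`, `C1`, `C` (M x M matrices),
#'   `rho` (training prevalence), `n_samples`, and `classifier_ids`.
#' @export
conditioned_moments <- function(ranks, labels) {
  ranks <- as_rank_matrix(ranks)
  labels <- as_labels(labels, n = ncol(ranks))
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("each class needs at least 2 samples for a class-conditioned covariance")
  }
  r1 <- ranks[, labels == 1L, drop = FALSE]
  r0 <- ranks[, labels == 0L, drop = FALSE]
  mu1 <- rowMeans(r1)
  mu0 <- rowMeans(r0)
  C1 <- pop_cov(r1)
  C0 <- pop_cov(r0)
  out <- list(mu0 = mu0, mu1 = mu1, delta = mu0 - mu1,
              C0 = C0, C1 = C1, C = C0 + C1,
              rho = mean(labels), n_samples = ncol(ranks),
              classifier_ids = rownames(ranks))
  class(out) <- "moca_moments"
  out
}

## Population covariance of the rows of an M x n matrix (divide by n).
pop_cov <- function(x) {
  xc <- x - rowMeans(x)
  tcrossprod(xc) / ncol(x)
}

#' SNR-optimal ensemble weights from class-conditioned moments
#'
#' The unit-norm weights maximizing the ensemble SNR,
#' \deqn{w = \frac{C^{-1}\Delta}{\|C^{-1}\Delta\|},}
#' the Fisher linear discriminant direction in rank space. When base
#' classifiers are class-conditionally independent, C is diagonal and the
#' weights reduce to \eqn{w_i \propto \Delta_i / (\sigma^2_{i|1} + \sigma^2_{i|0})}
#' — the functional form the unsupervised estimator targets.
#'
#' A singular C (e.g. duplicated classifiers) is an error by default; set
#' `ridge > 0` to solve with \eqn{C + ridge \cdot \bar{c} I} instead, where
#' \eqn{\bar{c}} is the mean diagonal entry of C.
#'
#' @param moments a `"moca_moments"` object from [conditioned_moments()], or a
#'   list with elements `delta` and `C`.
#' @param ridge nonnegative ridge fraction (default 0: no regularization).
#' @return numeric length-M unit-norm weight vector with attribute
#'   `source = "smoca"`, named by classifier when IDs are known.
#' @examples
#' m <- list(delta = c(1, 1), C = diag(c(1, 4)))
#' moca_weights(m)  # (0.9701, 0.2425)
#' @export
moca_weights <- function(moments, ridge = 0) {
  delta <- moments$delta
  C <- as_spsd(moments$C, length(delta))
  if (ridge < 0) stop("`ridge` must be nonnegative")
  A <- C + ridge * mean(diag(C)) * diag(length(delta))
  x <- tryCatch(solve(A, delta), error = function(e) {
    stop("C is singular: set ridge > 0 or drop duplicated classifiers")
  })
  w <- x / sqrt(sum(x^2))
  names(w) <- moments$classifier_ids
  attr(w, "source") <- "smoca"
  w
}

#' Ensemble score of a weighted rank matrix
#'
#' The linear ensemble score \eqn{s_k = \sum_i w_i r_{ik}}. Under the
#' rank-1-is-most-positive convention and weights aligned with \eqn{\Delta},
#' *smaller* ensemble scores indicate samples more likely to be positive;
#' every downstream metric in this package respects that orientation.
#'
#' @param ranks M x N rank matrix.
#' @param w length-M weight vector; when both `w` and the rank matrix carry
#'   classifier names they are aligned by name.
#' @return length-N numeric score vector, named by sample when IDs are known.
#' @export
ensemble_score <- function(ranks, w) {
  ranks <- as_rank_matrix(ranks)
  if (length(w) != nrow(ranks)) {
    stop(sprintf("weight length %d does not match %d classifiers", length(w), nrow(ranks)))
  }
  if (!is.null(names(w)) && !is.null(rownames(ranks))) {
    if (!setequal(names(w), rownames(ranks))) {
      stop("classifier IDs of `w` and `ranks` do not match")
    }
    w <- w[rownames(ranks)]
  }
  drop(crossprod(ranks, as.numeric(w)))
}

#' Greedy forward selection of base classifiers
#'
#' Builds an ensemble by forward selection on the training SNR: start from the
#' single classifier with the largest individual SNR, then repeatedly add the
#' classifier whose inclusion yields the largest optimal ensemble SNR
#' (recomputing the class-conditioned moments on each candidate subset), and
#' stop when no addition improves the criterion by more than a relative 1e-9.
#' Candidates that make C singular (e.g. exact duplicates) cannot improve the
#' criterion and are skipped. Ties are broken toward the lowest classifier
#' index.
#'
#' @inheritParams conditioned_moments
#' @param ridge ridge fraction passed to [moca_weights()] for the final fit.
#' @return length-M unit-norm weight vector; entries outside the selected
#'   subset are exactly zero. The selected indices are in attribute
#'   `"selected"`.
#' @export
greedy_select <- function(ranks, labels, ridge = 0) {
  ranks <- as_rank_matrix(ranks)
  labels <- as_labels(labels, n = ncol(ranks))
  m <- nrow(ranks)
  snr1 <- vapply(seq_len(m), function(i) {
    tryCatch(classifier_snr(ranks[i, ], labels), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(snr1))) stop("all classifiers are degenerate (constant within both classes)")

  subset_snr <- function(idx) {
    mom <- conditioned_moments(ranks[idx, , drop = FALSE], labels)
    A <- mom$C + ridge * mean(diag(mom$C)) * diag(length(idx))
    tryCatch(optimal_ensemble_snr(mom$delta, A), error = function(e) NA_real_)
  }

  selected <- which.max(snr1)                # lowest index wins ties
  best <- subset_snr(selected)
  repeat {
    candidates <- setdiff(seq_len(m), selected)
    if (length(candidates) == 0L) break
    crit <- vapply(candidates, function(j) subset_snr(sort(c(selected, j))), numeric(1))
    if (all(is.na(crit))) break
    j <- candidates[which.max(crit)]
    if (is.na(best) || max(crit, na.rm = TRUE) > best * (1 + 1e-9)) {
      selected <- sort(c(selected, j))
      best <- max(crit, na.rm = TRUE)
    } else break
  }

  mom <- conditioned_moments(ranks[selected, , drop = FALSE], labels)
  w_sub <- moca_weights(mom, ridge = ridge)
  w <- numeric(m)
  w[selected] <- w_sub
  names(w) <- rownames(ranks)
  attr(w, "source") <- "smoca"
  attr(w, "selected") <- selected
  w
}

#' Fit supervised MOCA weights
#'
#' Convenience composition of [conditioned_moments()] with either
#' [moca_weights()] (`select = FALSE`) or [greedy_select()] (`select = TRUE`).
#' Most users should call [moca()] instead, which wraps this in a fitted-model
#' object.
#'
#' @inheritParams greedy_select
#' @param select logical; run greedy forward selection of base classifiers.
#' @return unit-norm weight vector (attributes `source`, and `selected` when
#'   selection ran).
#' @export
fit_smoca <- function(ranks, labels, select = FALSE, ridge = 0) {
  if (select) {
    greedy_select(ranks, labels, ridge = ridge)
  } else {
    w <- moca_weights(conditioned_moments(ranks, labels), ridge = ridge)
    attr(w, "selected") <- seq_len(nrow(as_rank_matrix(ranks)))
    w
  }
}
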