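#' Unconditioned second- and third-order rank moments
#'
#' Computes the population covariance matrix `Q`, the third central-moment
#' tensor `T` (as an M x M x M array), and the per-classifier second and third
#' central moments of the rows of a rank matrix, centering each row by its
#' mean. These are the label-free sufficient statistics of the unsupervised
#' estimator: under a two-class mixture with class-conditionally independent
#' classifiers,
#' \deqn{Q_{ij} = \rho(1-\rho)\Delta_i\Delta_j \quad (i \ne j), \qquad
#'       T_{ijk} = \rho(1-\rho)(2\rho-1)\Delta_i\Delta_j\Delta_k \quad (i,j,k
#'       \textrm{ distinct}).}
#' For tie-free ranks the row moments are exact: `m2 = (N^2-1)/12` and
#' `m3 = 0` for every classifier.
#'
#' @param ranks M x N rank matrix, `N >= 3`.
#' @return list with `Q` (M x M), `T` (M x M x M), `m2`, `m3` (length M),
#'   `n_samples`, and `classifier_ids`.
#' @export
unconditional_moments <- function(ranks) {
  ranks <- as_rank_matrix(ranks)
  n <- ncol(ranks)
  if (n < 3L) stop("at least 3 samples are needed for third-order moments")
  m <- nrow(ranks)
  xc <- ranks - rowMeans(ranks)
  Q <- tcrossprod(xc) / n
  T <- array(0, dim = c(m, m, m))
  for (k in seq_len(m)) {
    T[, , k] <- (xc * rep(xc[k, ], each = m)) %*% t(xc) / n
  }
  list(Q = Q, T = T, m2 = diag(Q), m3 = rowMeans(xc^3),
       n_samples = n, classifier_ids = rownames(ranks))
}

#' Rank-one fit of a covariance matrix by diagonal imputation
#'
#' Fits \eqn{Q \approx \ell\, u u^\top} using only the off-diagonal entries
#' (the diagonal carries conditional-variance terms that are not part of the
#' rank-one signal). The iteration starts from the observed diagonal and
#' alternates: take the leading eigenpair of the current matrix, then replace
#' the diagonal with the diagonal of \eqn{\ell u u^\top}, until the diagonal
#' stops changing. The sign of the returned vector is fixed so that its
#' entries sum to a positive value (the average classifier is assumed better
#' than random).
#'
#' @param Q symmetric M x M covariance matrix, `M >= 3`.
#' @param tol convergence tolerance on the imputed diagonal (relative).
#' @param max_iter iteration cap.
#' @return list with `q` (\eqn{= \sqrt{\ell}\, u}, length M), `ell` (the
#'   leading eigenvalue \eqn{\ell \ge 0}), `u` (unit vector), `n_iter`,
#'   `converged`.
#' @export
rank_one_covariance_fit <- function(Q, tol = 1e-6, max_iter = 1000L) {
  m <- nrow(Q)
  if (m < 3L) stop("M >= 3 classifiers are required (off-diagonal system identifiable)")
  Q <- as_spsd(Q, m)
  A <- Q
  scale <- max(abs(diag(Q)), 1e-12)
  converged <- FALSE
  iter <- 0L
  ell <- 0
  u <- numeric(m)
  while (iter < max_iter) {
    iter <- iter + 1L
    e <- eigen(A, symmetric = TRUE)
    ell <- e$values[1L]
    u <- e$vectors[, 1L]
    if (ell < -tol * scale) {
      stop("leading eigenvalue is negative: inconsistent with a rank-one mixture signal")
    }
    newdiag <- ell * u^2
    if (max(abs(newdiag - diag(A))) < tol * scale) {
      diag(A) <- newdiag
      converged <- TRUE
      break
    }
    diag(A) <- newdiag
  }
  if (sum(u) < 0) u <- -u
  ell <- max(ell, 0)
  list(q = sqrt(ell) * u, ell = ell, u = u, n_iter = iter, converged = converged)
}

## Mask of strictly off-diagonal (all indices distinct) entries of an
## M x M x M tensor.
distinct_index_mask <- function(m) {
  idx <- expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m))
  mask <- array(FALSE, dim = c(m, m, m))
  keep <- idx$i != idx$j & idx$j != idx$k & idx$i != idx$k
  mask[cbind(idx$i, idx$j, idx$k)[keep, , drop = FALSE]] <- TRUE
  mask
}

#' Single-factor CP fit of the third central-moment tensor
#'
#' Fits \eqn{T_{ijk} \approx t_i t_j t_k} over the entries with all indices
#' distinct (repeated-index entries mix the rank-one signal with
#' conditional-variance terms and are excluded), by alternating least
#' squares. Unlike the covariance fit, the sign of `t` is identified by the
#' data: an odd-order product flips sign with `t`.
#'
#' @param T M x M x M third central-moment tensor, `M >= 3`.
#' @param tol relative convergence tolerance on the factor.
#' @param max_iter iteration cap.
#' @param init optional length-M initial factor; defaults to a spectral
#'   initialization from the mode-collapsed tensor.
#' @return list with `t` (length M), `n_iter`, `converged`, `identifiable`
#'   (FALSE when the off-diagonal tensor is numerically zero, the prevalence
#'   1/2 degeneracy).
#' @export
rank_one_tensor_fit <- function(T, tol = 1e-6, max_iter = 1000L, init = NULL) {
  m <- dim(T)[1L]
  if (length(dim(T)) != 3L || any(dim(T) != m)) stop("T must be an M x M x M array")
  if (m < 3L) stop("M >= 3 classifiers are required")
  mask <- distinct_index_mask(m)
  toff <- T * mask
  tscale <- max(abs(toff))
  if (tscale < 1e-12) {
    return(list(t = numeric(m), n_iter = 0L, converged = TRUE, identifiable = FALSE))
  }
  if (is.null(init)) {
    ## spectral init: collapse one mode (off-diagonal only), leading eigenvector
    S <- matrix(0, m, m)
    for (k in seq_len(m)) S <- S + toff[, , k]
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    v <- e$vectors[, which.max(abs(e$values))]
    init <- v
  }
  u0 <- init / sqrt(sum(init^2))
  c0 <- cp_project(toff, mask, u0)
  t_vec <- sign(c0) * abs(c0)^(1 / 3) * u0
  if (all(t_vec == 0)) t_vec <- rep(tscale^(1 / 3) / m, m)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    t_old <- t_vec
    for (i in seq_len(m)) {
      tt <- outer(t_vec, t_vec)
      mi <- mask[i, , ]
      num <- sum(toff[i, , ] * tt * mi)
      den <- sum((tt^2) * mi)
      t_vec[i] <- if (den > 0) num / den else 0
    }
    if (max(abs(t_vec - t_old)) < tol * max(abs(t_vec), tscale^(1 / 3))) {
      converged <- TRUE
      break
    }
  }
  list(t = t_vec, n_iter = iter, converged = converged, identifiable = TRUE)
}

## Least-squares scale of T along u x u x u restricted to distinct indices.
cp_project <- function(toff, mask, u) {
  cube <- outer(outer(u, u), u)
  dim(cube) <- dim(toff)
  num <- sum(toff * cube * mask)
  den <- sum((cube^2) * mask)
  if (den > 0) num / den else 0
}

#' Infer prevalence and class-mean separations from rank-one fits
#'
#' Under class-conditioned independence the off-diagonal covariance is
#' \eqn{\rho(1-\rho)\Delta\Delta^\top} and the off-diagonal tensor is
#' \eqn{\rho(1-\rho)(2\rho-1)\,\Delta\otimes\Delta\otimes\Delta}. Writing
#' \eqn{\ell} for the covariance scale and \eqn{c} for the tensor scale along
#' the covariance direction, the combined scalar
#' \deqn{\gamma = -c/\ell^{3/2} = \frac{1-2\rho}{\sqrt{\rho(1-\rho)}}}
#' determines the prevalence through the quadratic
#' \eqn{(4+\gamma^2)\rho^2 - (4+\gamma^2)\rho + 1 = 0}, taking the root below
#' 1/2 when \eqn{\gamma > 0}. The separations follow as
#' \eqn{\hat\Delta = q/\sqrt{\hat\rho(1-\hat\rho)}}. The joint sign ambiguity
#' (\eqn{\Delta \to -\Delta}, \eqn{\rho \to 1-\rho} leaves all moments
#' unchanged) is resolved by requiring a majority of positive separations.
#'
#' @param q length-M vector \eqn{\sqrt{\ell}u} from [rank_one_covariance_fit()].
#' @param ell leading covariance eigenvalue \eqn{\ell > 0}.
#' @param t length-M tensor factor from [rank_one_tensor_fit()].
#' @return list with `rho_hat`, `delta_hat` (length M), `gamma`, and
#'   `identifiable` (FALSE when \eqn{\gamma \approx 0}: the prevalence is then
#'   fixed at 1/2 with a warning, separations remain recoverable).
#' @export
infer_prevalence_delta <- function(q, ell, t) {
  if (ell <= 0) stop("`ell` must be positive: no rank-one covariance signal")
  u <- q / sqrt(sum(q^2))
  cc <- sum(t * u)^3            # tensor scale along the covariance direction
  gamma <- -cc / ell^(3 / 2)
  identifiable <- abs(gamma) > 1e-6
  if (!identifiable) {
    warning("third-moment signal is ~0 (prevalence near 1/2): fixing rho_hat = 0.5")
    rho <- 0.5
    gamma <- 0
  } else {
    rho <- 0.5 * (1 - gamma / sqrt(4 + gamma^2))
  }
  delta <- q / sqrt(rho * (1 - rho))
  if (mean(delta > 0) < 0.5) {  # joint sign flip keeps all moments invariant
    delta <- -delta
    rho <- 1 - rho
    gamma <- -gamma
  }
  list(rho_hat = rho, delta_hat = delta, gamma = gamma, identifiable = identifiable)
}

#' Conditional-variance sums from unconditioned moments
#'
#' Solves, per classifier, the two-component mixture moment identities
#' \deqn{m_2 = \rho\sigma^2_{|1} + (1-\rho)\sigma^2_{|0} + \rho(1-\rho)\Delta^2}
#' \deqn{m_3 = 3\rho(1-\rho)\Delta(\sigma^2_{|0} - \sigma^2_{|1})
#'             + \rho(1-\rho)(2\rho-1)\Delta^3}
#' (conditional third moments taken as zero) for \eqn{(\sigma^2_{|0},
#' \sigma^2_{|1})} and returns the sum \eqn{\sigma^2_{|0} + \sigma^2_{|1}} —
#' the denominator of the independent-classifier weights. For tie-free ranks,
#' where \eqn{m_2 = (N^2-1)/12} and \eqn{m_3 = 0} exactly, the sum reduces to
#' \eqn{(N^2-1)/6 - \Delta^2[2\rho(1-\rho) + (1-2\rho)^2/3]}.
#'
#' When \eqn{|\Delta_i|} is numerically zero the skew equation is ill-posed;
#' the skew term is dropped (equal-variance fallback) and the entry is
#' flagged. Non-positive solutions are floored at a small positive value and
#' flagged rather than allowed to flip the sign of the weights.
#'
#' @param m2,m3 length-M second and third central moments (from
#'   [unconditional_moments()]).
#' @param rho_hat prevalence estimate in (0, 1).
#' @param delta_hat length-M separation estimates.
#' @return length-M vector of variance sums, with logical attribute
#'   `"flagged"` marking fallback/floored entries.
#' @export
variance_sums <- function(m2, m3, rho_hat, delta_hat) {
  if (rho_hat <= 0 || rho_hat >= 1) stop("`rho_hat` must lie in (0, 1)")
  m <- length(m2)
  stopifnot(length(m3) == m, length(delta_hat) == m)
  p <- rho_hat * (1 - rho_hat)
  A <- m2 - p * delta_hat^2                     # rho*s2_1 + (1-rho)*s2_0
  dtol <- 1e-8 * sqrt(max(m2, 1))
  flagged <- logical(m)
  D <- numeric(m)                               # s2_0 - s2_1
  ok <- abs(delta_hat) > dtol
  D[ok] <- (m3[ok] - p * (2 * rho_hat - 1) * delta_hat[ok]^3) /
    (3 * p * delta_hat[ok])
  flagged[!ok] <- TRUE
  out <- 2 * A + (2 * rho_hat - 1) * D
  eps <- 1e-6 * max(m2, 1)
  bad <- out <= 0
  out[bad] <- eps
  flagged <- flagged | bad
  attr(out, "flagged") <- flagged
  out
}

#' Fit unsupervised MOCA weights
#'
#' Full label-free pipeline: unconditioned moments, rank-one covariance and
#' tensor fits, prevalence/separation inference, conditional-variance sums,
#' then the independence-form weights
#' \deqn{w_i = \beta\,\hat\Delta_i \big/ (\hat\sigma^2_{i|0} + \hat\sigma^2_{i|1}),}
#' normalized to unit Euclidean norm. No argument of this function carries
#' labels; the estimator is unsupervised by construction and is optimal when
#' base classifiers are class-conditionally independent.
#'
#' @param ranks M x N rank matrix, `M >= 3`, `N >= 3`.
#' @param tol convergence tolerance for both rank-one fits.
#' @param max_iter iteration cap for both rank-one fits.
#' @return list with `weights` (unit-norm, attribute `source = "umoca"`) and
#'   `estimates`, a list holding `rho_hat`, `delta_hat`, `var_sums`,
#'   `cov_eigenvalue`, `tensor_scale`, `gamma`, `n_iter`, `converged`, and
#'   `flagged`.
#' @seealso [moca()] for the fitted-model interface.
#' @export
fit_umoca <- function(ranks, tol = 1e-6, max_iter = 1000L) {
  ranks <- as_rank_matrix(ranks)
  if (nrow(ranks) < 3L) {
    stop("unsupervised fitting needs M >= 3 classifiers (moment system unidentifiable)")
  }
  mom <- unconditional_moments(ranks)
  cf <- rank_one_covariance_fit(mom$Q, tol = tol, max_iter = max_iter)
  tf <- rank_one_tensor_fit(mom$T, tol = tol, max_iter = max_iter, init = cf$u)
  if (!tf$identifiable) {
    warning("off-diagonal third-moment tensor is ~0: prevalence fixed at 1/2")
    inf <- list(rho_hat = 0.5, delta_hat = cf$q / sqrt(0.25), gamma = 0,
                identifiable = FALSE)
    if (mean(inf$delta_hat > 0) < 0.5) inf$delta_hat <- -inf$delta_hat
  } else {
    inf <- infer_prevalence_delta(cf$q, cf$ell, tf$t)
  }
  vs <- variance_sums(mom$m2, mom$m3, inf$rho_hat, inf$delta_hat)
  w <- inf$delta_hat / vs
  w <- w / sqrt(sum(w^2))
  names(w) <- rownames(ranks)
  attr(w, "source") <- "umoca"
  estimates <- list(
    rho_hat = inf$rho_hat,
    delta_hat = inf$delta_hat,
    var_sums = as.numeric(vs),
    cov_eigenvalue = cf$ell,
    tensor_scale = sum(tf$t * cf$u)^3,
    gamma = inf$gamma,
    n_iter = c(covariance = cf$n_iter, tensor = tf$n_iter),
    converged = cf$converged && tf$converged,
    identifiable = inf$identifiable,
    flagged = attr(vs, "flagged")
  )
  list(weights = w, estimates = estimates)
}
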