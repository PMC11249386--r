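#' Fit an SNR-optimal linear ensemble of rank-calibrated classifiers
#'
#' The main entry point. Given an M x N matrix of within-classifier sample
#' ranks (use [rank_transform()] on raw scores first), fits linear ensemble
#' weights by one of four methods:
#'
#' * `"smoca"` — supervised: unit-norm weights \eqn{w \propto C^{-1}\Delta}
#'   from empirical class-conditioned rank moments, optionally with greedy
#'   forward selection of base classifiers. Requires `labels`.
#' * `"umoca"` — unsupervised: the same weights under class-conditioned
#'   independence, with prevalence, separations and conditional-variance sums
#'   inferred from second- and third-order moments of the unlabeled ranks.
#' * `"woc"` — wisdom of crowds: all weights equal to 1 (rank-sum ensemble).
#' * `"best_bc"` — the single classifier with the highest training AUC
#'   (requires `labels`).
#'
#' The default `"auto"` picks `"smoca"` when labels are supplied and
#' `"umoca"` otherwise. Ensemble scores from the fitted weights follow the
#' smaller-is-positive orientation throughout.
#'
#' @param ranks M x N rank matrix; rows are classifiers, columns samples.
#' @param labels optional 0/1 vector of length N (1 = positive class).
#' @param method one of `"auto"`, `"smoca"`, `"umoca"`, `"woc"`, `"best_bc"`.
#' @param select logical; greedy forward selection (supervised method only).
#' @param ridge nonnegative ridge fraction for a singular pooled covariance
#'   (supervised method only; default 0 = hard error on singularity).
#' @param tol,max_iter convergence controls for the unsupervised rank-one
#'   fits.
#' @return an object of class `"moca"`: a list with components
#'   \describe{
#'     \item{weights}{named length-M weight vector (unit norm for
#'       smoca/umoca).}
#'     \item{method}{the method actually used.}
#'     \item{selected}{indices of classifiers in the ensemble.}
#'     \item{estimates}{unsupervised estimates (`rho_hat`, `delta_hat`,
#'       `var_sums`, `gamma`, convergence diagnostics), `NULL` otherwise.}
#'     \item{moments}{class-conditioned moments (supervised), `NULL`
#'       otherwise.}
#'     \item{train_snr}{training ensemble SNR where labels permit,
#'       otherwise `NA`.}
#'   }
#' @examples
#' sim <- simulate_predictions(seq(0.6, 0.8, length.out = 4), 0.3, 200, seed = 1)
#' fit <- moca(sim$ranks, sim$labels)         # supervised
#' ufit <- moca(sim$ranks)                    # unsupervised
#' coef(fit)
#' head(predict(fit, sim$ranks))
#' @export
moca <- function(ranks, labels = NULL,
                 method = c("auto", "smoca", "umoca", "woc", "best_bc"),
                 select = FALSE, ridge = 0, tol = 1e-6, max_iter = 1000L) {
  method <- match.arg(method)
  ranks <- as_rank_matrix(ranks)
  m <- nrow(ranks)
  if (method == "auto") method <- if (is.null(labels)) "umoca" else "smoca"
  if (method %in% c("smoca", "best_bc") && is.null(labels)) {
    stop(sprintf("method '%s' requires labels", method))
  }
  if (!is.null(labels)) labels <- as_labels(labels, n = ncol(ranks))

  estimates <- NULL
  moments <- NULL
  selected <- seq_len(m)
  if (method == "smoca") {
    w <- fit_smoca(ranks, labels, select = select, ridge = ridge)
    selected <- attr(w, "selected")
    moments <- conditioned_moments(ranks, labels)
  } else if (method == "umoca") {
    fit <- fit_umoca(ranks, tol = tol, max_iter = max_iter)
    w <- fit$weights
    estimates <- fit$estimates
  } else if (method == "woc") {
    w <- woc_weights(m)
    names(w) <- rownames(ranks)
  } else { # best_bc
    a <- apply(ranks, 1L, auc_rank, labels = labels)
    selected <- which.max(a)
    w <- numeric(m)
    w[selected] <- 1
    names(w) <- rownames(ranks)
    attr(w, "source") <- "best_bc"
  }

  train_snr <- NA_real_
  if (!is.null(labels)) {
    mom <- if (is.null(moments)) conditioned_moments(ranks, labels) else moments
    train_snr <- ensemble_snr(as.numeric(w), mom$delta, mom$C)
  }

  structure(list(weights = w, method = method, selected = selected,
                 estimates = estimates, moments = moments,
                 train_snr = train_snr, n_classifiers = m,
                 n_samples = ncol(ranks),
                 classifier_ids = rownames(ranks), call = match.call()),
            class = "moca")
}

#' @export
print.moca <- function(x, digits = 4L, ...) {
  cat(sprintf("MOCA ensemble fit (%s): %d classifiers, %d samples\n",
              x$method, x$n_classifiers, x$n_samples))
  if (length(x$selected) < x$n_classifiers) {
    cat(sprintf("  selected %d of %d classifiers\n",
                length(x$selected), x$n_classifiers))
  }
  if (!is.null(x$estimates)) {
    cat(sprintf("  inferred prevalence: %.3f (gamma = %.3f)\n",
                x$estimates$rho_hat, x$estimates$gamma))
  }
  if (is.finite(x$train_snr)) {
    cat(sprintf("  training ensemble SNR: %.3f (AUC %.3f)\n",
                x$train_snr, snr_to_auc(x$train_snr)))
  }
  cat("Weights:\n")
  print(round(as.numeric(x$weights), digits))
  invisible(x)
}

#' @export
coef.moca <- function(object, ...) {
  w <- as.numeric(object$weights)
  names(w) <- object$classifier_ids
  w
}

#' Ensemble scores or hard class predictions from a fitted ensemble
#'
#' @param object a fitted `"moca"` object.
#' @param ranks M x N rank matrix to score (re-rank new scores with
#'   [rank_transform()] first). Classifier rows are aligned by name when both
#'   sides are named.
#' @param type `"score"` (default) for continuous ensemble scores (smaller =
#'   more likely positive) or `"class"` for hard 0/1 predictions at
#'   prevalence `rho`.
#' @param rho prevalence used by `type = "class"`; defaults to the training
#'   prevalence (supervised fits) or the inferred prevalence (unsupervised
#'   fits).
#' @param ... unused.
#' @return length-N numeric scores, or integer 0/1 predictions.
#' @export
predict.moca <- function(object, ranks, type = c("score", "class"), rho = NULL, ...) {
  type <- match.arg(type)
  s <- ensemble_score(ranks, object$weights)
  if (type == "score") return(s)
  if (is.null(rho)) {
    rho <- if (!is.null(object$estimates)) object$estimates$rho_hat
           else if (!is.null(object$moments)) object$moments$rho
    if (is.null(rho)) stop("supply `rho` for class predictions with this fit")
  }
  binarize_by_prevalence(s, rho)
}

#' @export
summary.moca <- function(object, ...) {
  tab <- data.frame(classifier = object$classifier_ids %||% seq_len(object$n_classifiers),
                    weight = as.numeric(object$weights))
  if (!is.null(object$moments)) {
    tab$delta <- object$moments$delta
    tab$var_sum <- diag(object$moments$C)
    tab$snr <- tab$delta / sqrt(tab$var_sum)
    tab$auc <- snr_to_auc(tab$snr)
  } else if (!is.null(object$estimates)) {
    tab$delta_hat <- object$estimates$delta_hat
    tab$var_sum_hat <- object$estimates$var_sums
    tab$snr_hat <- tab$delta_hat / sqrt(tab$var_sum_hat)
    tab$auc_hat <- snr_to_auc(tab$snr_hat)
  }
  out <- list(fit = object, table = tab)
  class(out) <- "summary.moca"
  out
}

#' @export
print.summary.moca <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-classifier estimates:\n")
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot ensemble weights
#'
#' Barplot of the fitted weights, one bar per base classifier.
#'
#' @param x a fitted `"moca"` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.moca <- function(x, ...) {
  graphics::barplot(as.numeric(x$weights),
                    names.arg = x$classifier_ids %||% seq_len(x$n_classifiers),
                    ylab = "weight", las = 2,
                    main = sprintf("%s ensemble weights", x$method), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
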