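#' Rank-based AUC with a smaller-is-positive orientation
#'
#' The Mann-Whitney statistic: the fraction of (positive, negative) sample
#' pairs in which the positive sample has the *smaller* value, with half
#' credit for ties. This matches the package-wide orientation in which low
#' ranks and low ensemble scores indicate positive-leaning predictions, so a
#' better-than-random classifier scores above 0.5.
#'
#' @param values length-N numeric vector (ranks or ensemble scores; smaller =
#'   more likely positive).
#' @param labels 0/1 vector of length N.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(values, labels) {
  labels <- as_labels(labels, n = length(values))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(values, ties.method = "average")      # ascending
  u_gt <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2  # pairs with positive larger
  1 - u_gt / (n1 * n0)
}

#' Hard class predictions at a prevalence threshold
#'
#' Predicts positive the `round(rho * N)` samples with the smallest ensemble
#' scores (equivalently, thresholds at the rho-quantile of the scores), with a
#' deterministic tie-break by sample index. This converts continuous ensemble
#' scores into labels for balanced accuracy and F1 without fitting a
#' threshold.
#'
#' @param scores length-N ensemble scores (smaller = more likely positive).
#' @param rho assumed positive-class prevalence in (0, 1), typically the
#'   training-set prevalence.
#' @return integer 0/1 vector of hard predictions.
#' @export
binarize_by_prevalence <- function(scores, rho) {
  if (rho <= 0 || rho >= 1) stop("`rho` must lie in (0, 1)")
  n <- length(scores)
  n1 <- round(rho * n)
  pred <- integer(n)
  pred[order(scores)[seq_len(n1)]] <- 1L   # order() breaks ties by index
  pred
}

#' Balanced accuracy and F1 score
#'
#' `balanced_accuracy` is \eqn{(TPR + TNR)/2}; `f1_score` is the harmonic mean
#' of precision and recall, defined as 0 when precision + recall is 0.
#'
#' @param pred 0/1 hard predictions.
#' @param labels 0/1 true labels (both classes present).
#' @return a scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(pred, labels) {
  labels <- as_labels(labels, n = length(pred))
  tpr <- sum(pred == 1L & labels == 1L) / sum(labels == 1L)
  tnr <- sum(pred == 0L & labels == 0L) / sum(labels == 0L)
  (tpr + tnr) / 2
}

#' @rdname balanced_accuracy
#' @export
f1_score <- function(pred, labels) {
  labels <- as_labels(labels, n = length(pred))
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Wisdom-of-crowds weights
#'
#' The equal-weights baseline: every classifier gets weight 1, so the
#' ensemble score is the plain rank sum across classifiers.
#'
#' @param m number of classifiers.
#' @return length-M vector of ones with attribute `source = "woc"`.
#' @export
woc_weights <- function(m) {
  if (m < 1) stop("`m` must be >= 1")
  w <- rep(1, m)
  attr(w, "source") <- "woc"
  w
}

#' Stratified cross-validation of aggregation methods
#'
#' Runs repeated stratified k-fold cross-validation: per fold, weights are fit
#' on the training columns (the unsupervised method ignores the training
#' labels by contract; the wisdom-of-crowds baseline needs no fitting; the
#' best-individual baseline picks the classifier with the highest training
#' AUC), test columns are *re-ranked within the test split* so rank scales
#' match the split size, and AUC, balanced accuracy and F1 are computed on the
#' test ensemble scores. Hard labels for BA/F1 come from
#' [binarize_by_prevalence()] at the training prevalence.
#'
#' @param ranks M x N rank matrix.
#' @param labels 0/1 vector of length N (used for stratification, training
#'   fits where the method is supervised, and test metrics).
#' @param method one of `"smoca"`, `"umoca"`, `"woc"`, `"best_bc"`.
#' @param folds number of folds (default 5).
#' @param repeats number of independent fold partitions (default 1).
#' @param seed integer seed for the fold partitions.
#' @param select,ridge passed to [fit_smoca()] when `method = "smoca"`.
#' @return object of class `"moca_cv"`: list with `folds` (long data frame:
#'   method, metric, repeat, fold, value) and `summary` (method, metric, mean,
#'   sem over all folds of all repeats).
#' @export
cross_validate <- function(ranks, labels, method = c("smoca", "umoca", "woc", "best_bc"),
                           folds = 5L, repeats = 1L, seed = 1L,
                           select = FALSE, ridge = 0) {
  method <- match.arg(method)
  ranks <- as_rank_matrix(ranks)
  labels <- as_labels(labels, n = ncol(ranks))
  n <- ncol(ranks)
  if (min(sum(labels == 1L), sum(labels == 0L)) < folds) {
    stop(sprintf("too few samples per class for %d stratified folds: need at least %d per class",
                 folds, folds))
  }
  rows <- list()
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (rep_i in seq_len(repeats)) {
    fold_id <- stratified_folds(labels, folds)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      r_train <- rerank(ranks[, !test, drop = FALSE])
      r_test <- rerank(ranks[, test, drop = FALSE])
      y_train <- labels[!test]
      y_test <- labels[test]
      w <- switch(method,
        smoca = fit_smoca(r_train, y_train, select = select, ridge = ridge),
        umoca = fit_umoca(r_train)$weights,
        woc = woc_weights(nrow(ranks)),
        best_bc = {
          a <- apply(r_train, 1L, auc_rank, labels = y_train)
          w0 <- numeric(nrow(ranks))
          w0[which.max(a)] <- 1
          w0
        })
      s <- ensemble_score(r_test, w)
      pred <- binarize_by_prevalence(s, mean(y_train))
      vals <- c(auc = auc_rank(s, y_test),
                ba = balanced_accuracy(pred, y_test),
                f1 = f1_score(pred, y_test))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, metric = names(vals), rep = rep_i, fold = f,
        value = unname(vals), stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(long, long$metric), function(d) {
    data.frame(method = method, metric = d$metric[1L], mean = mean(d$value),
               sem = stats::sd(d$value) / sqrt(nrow(d)), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  out <- list(folds = long, summary = summ, method = method,
              n_folds = folds, repeats = repeats)
  class(out) <- "moca_cv"
  out
}

## Re-rank a rank (or score) submatrix within a split: ranking is monotone in
## -score and ranks are monotone in score, so ranking -ranks restores the
## 1..n_split scale.
rerank <- function(ranks) rank_transform(-ranks)

## Stratified fold assignment: shuffles each class and deals it round-robin.
stratified_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(labels == cls))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' @export
print.moca_cv <- function(x, ...) {
  cat(sprintf("Cross-validation: %s, %d fold(s) x %d repeat(s)\n",
              x$method, x$n_folds, x$repeats))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.4f +/- %.4f (SEM)\n", s$metric[i], s$mean[i], s$sem[i]))
  }
  invisible(x)
}
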