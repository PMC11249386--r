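#' Rank-calibrate classifier scores
#'
#' Converts a matrix of raw classifier scores (one row per base classifier,
#' one column per sample) into within-classifier sample ranks. The convention
#' follows the rank-1-is-most-positive orientation: within each row, the sample
#' with the *largest* score receives rank 1, so low ranks indicate samples a
#' classifier considers most likely to belong to the positive class. Tied
#' scores receive the average of the ranks they span, which keeps every row
#' sum equal to \eqn{N(N+1)/2} and makes the rank-based AUC coincide with the
#' Mann-Whitney statistic with half credit for ties.
#'
#' Ranking is invariant under any strictly increasing transform of a row's
#' scores, which is what makes ranks a scale-free calibration across
#' heterogeneous classifiers (probabilities, margins, correlation scores, ...).
#'
#' @param scores numeric matrix, M classifiers x N samples. Row names identify
#'   classifiers, column names identify samples (both optional). `N >= 2`.
#' @return numeric matrix of the same dimension and dimnames; each row holds
#'   ranks in `[1, N]` summing to `N(N+1)/2`.
#' @examples
#' rank_transform(rbind(a = c(0.1, 0.9, 0.5)))         # 3 1 2
#' rank_transform(rbind(a = c(0.5, 0.5, 0.1)))         # 1.5 1.5 3
#' @seealso [read_scores()] to load a delimited score matrix from disk.
#' @export
rank_transform <- function(scores) {
  scores <- as_score_matrix(scores)
  ranks <- t(apply(scores, 1L, function(row) rank(-row, ties.method = "average")))
  dimnames(ranks) <- dimnames(scores)
  ranks
}

## Coerce and validate an M x N score matrix. Missing values are rejected
## (the rank algebra assumes complete rankings), naming the offending cell.
as_score_matrix <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.vector(scores) && is.numeric(scores)) scores <- matrix(scores, nrow = 1L)
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("`scores` must be a numeric matrix (M classifiers x N samples)")
  }
  if (ncol(scores) < 2L) stop("at least 2 samples (columns) are required to rank")
  bad <- which(!is.finite(scores), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cl <- if (is.null(rownames(scores))) bad[1L, 1L] else rownames(scores)[bad[1L, 1L]]
    sm <- if (is.null(colnames(scores))) bad[1L, 2L] else colnames(scores)[bad[1L, 2L]]
    stop(sprintf("missing or non-finite score for classifier '%s', sample '%s'", cl, sm))
  }
  scores
}

## Validate an M x N rank matrix: every row must hold values in [1, N] with
## the exact rank-sum N(N+1)/2 (holds for average-rank ties as well).
as_rank_matrix <- function(ranks) {
  ranks <- as_score_matrix(ranks)
  n <- ncol(ranks)
  if (any(ranks < 1 - 1e-8) || any(ranks > n + 1e-8)) {
    stop("rank entries must lie in [1, N]; did you pass raw scores instead of ranks?")
  }
  target <- n * (n + 1) / 2
  sums <- rowSums(ranks)
  if (any(abs(sums - target) > 1e-6 * target)) {
    stop("each row of a rank matrix must sum to N(N+1)/2; ",
         "use rank_transform() to calibrate scores first")
  }
  ranks
}

#' Read a delimited classifier score (or rank) matrix
#'
#' Reads a comma- (`.csv`) or tab-separated (`.tsv`, `.txt`) file whose first
#' row holds sample identifiers and whose first column holds classifier
#' identifiers. Use `transpose = TRUE` for files laid out samples x
#' classifiers.
#'
#' @param path path to the delimited file.
#' @param transpose logical; set `TRUE` when rows are samples and columns are
#'   classifiers.
#' @return numeric matrix, classifiers in rows, samples in columns, with
#'   dimnames taken from the file.
#' @export
read_scores <- function(path, transpose = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (transpose) m <- t(m)
  m
}

#' Read a binary label vector
#'
#' Reads class labels from a one- or two-column delimited file: either a bare
#' column of 0/1 values, or `sample_id,label` pairs (values are aligned to
#' `sample_ids` when both are available).
#'
#' @param path path to the delimited file.
#' @param sample_ids optional character vector used to reorder labelled files.
#' @return integer vector of 0/1 labels, named by sample when names are known.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(df) == 1L) {
    y <- as.integer(df[[1L]])
  } else {
    y <- as.integer(df[[2L]])
    names(y) <- as.character(df[[1L]])
    if (!is.null(sample_ids)) {
      if (!all(sample_ids %in% names(y))) stop("labels are missing some sample IDs")
      y <- y[sample_ids]
    }
  }
  as_labels(y)
}

## Validate a 0/1 label vector with both classes present.
as_labels <- function(labels, n = NULL) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("`labels` must be a vector of 0/1 values without missing entries")
  }
  if (!is.null(n) && length(labels) != n) {
    stop(sprintf("expected %d labels, got %d", n, length(labels)))
  }
  if (sum(labels == 1L) < 1L || sum(labels == 0L) < 1L) {
    stop("both classes must be present in `labels`")
  }
  labels
}
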