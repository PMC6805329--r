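# Micro-averaged multi-label metrics and the k-fold cross-validation harness.

#' Micro-averaged precision, recall and F1
#'
#' Counts true/false positives and false negatives summed over all labels:
#' `precision = sum tp / (sum tp + sum fp)`, `recall = sum tp / (sum tp +
#' sum fn)`, `F1 = 2PR / (P + R)`. Empty denominators yield 0 with a
#' warning.
#'
#' @param Y_true,Y_pred binary matrices of equal shape.
#' @return named numeric vector `(precision, recall, f1)`.
#' @export
micro_prf <- function(Y_true, Y_pred) {
  stopifnot(all(dim(Y_true) == dim(Y_pred)))
  if (!all(Y_true %in% c(0, 1)) || !all(Y_pred %in% c(0, 1)))
    stop("micro_prf expects binary matrices")
  tp <- sum(Y_true == 1 & Y_pred == 1)
  fp <- sum(Y_true == 0 & Y_pred == 1)
  fn <- sum(Y_true == 1 & Y_pred == 0)
  guard <- function(num, den, what) {
    if (den == 0) { warning(what, ": empty denominator, reporting 0"); 0 }
    else num / den
  }
  precision <- guard(tp, tp + fp, "precision")
  recall <- guard(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Multi-label ranking loss
#'
#' Mean over samples of the fraction of (true, false) label pairs where the
#' true label's score is strictly below the false label's:
#' `|{(k, l): score_k < score_l, y_k = 1, y_l = 0}| / (|y| (m - |y|))`.
#' Ties are not counted as incorrect. Samples whose truth row is all-ones or
#' all-zeros have an undefined denominator and are skipped with a warning.
#'
#' @param Y_true binary n x m matrix.
#' @param scores numeric n x m score matrix.
#' @return scalar in \[0, 1\].
#' @export
ranking_loss <- function(Y_true, scores) {
  stopifnot(all(dim(Y_true) == dim(scores)))
  m <- ncol(Y_true)
  per_sample <- vapply(seq_len(nrow(Y_true)), function(i) {
    y <- Y_true[i, ]; s <- scores[i, ]
    npos <- sum(y == 1)
    if (npos == 0 || npos == m) return(NA_real_)
    pos <- s[y == 1]; neg <- s[y == 0]
    bad <- sum(outer(pos, neg, "<"))
    bad / (npos * (m - npos))
  }, numeric(1))
  if (anyNA(per_sample)) {
    warning(sum(is.na(per_sample)),
            " sample(s) with degenerate label rows skipped in ranking loss")
    per_sample <- per_sample[!is.na(per_sample)]
  }
  if (length(per_sample) == 0) return(NaN)
  mean(per_sample)
}

#' Random fold assignment
#'
#' Random equal split: fold sizes differ by at most one, folds are disjoint
#' and cover all samples; deterministic given `seed`.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k, seed = 1) {
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' k-fold cross-validation
#'
#' Trains on k-1 folds and evaluates on the held-out fold; reports per-fold
#' and mean micro precision/recall/F1 and ranking loss. The trainer is any
#' function `(X, Y, train_idx, test_idx, fold_seed) -> n_test x m score
#' matrix`, so MetaMLAnn, IDW (which scores from coordinates, not features)
#' or an ensemble all plug in; see [metamlann_trainer()] and
#' [idw_trainer()].
#'
#' @param X n x k feature matrix (any row-indexable object the trainer
#'   understands).
#' @param Y n x m binary label matrix.
#' @param k number of folds (default 3).
#' @param trainer scoring function (see details).
#' @param seed RNG seed for the fold split and, via `fold_seed`, the trainer.
#' @param threshold presence cut for binarizing scores (default 0.5).
#' @return list with `folds` (data.frame of per-fold metrics), `mean`
#'   (named vector) and the fold `assignments`.
#' @export
kfold_cv <- function(X, Y, k = 3, trainer, seed = 1, threshold = 0.5) {
  n <- nrow(Y)
  folds <- make_folds(n, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    test <- which(folds == f); train <- which(folds != f)
    scores <- trainer(X, Y, train, test, seed + f)
    preds <- (scores >= threshold) * 1L
    prf <- micro_prf(Y[test, , drop = FALSE], preds)
    rl <- suppressWarnings(ranking_loss(Y[test, , drop = FALSE], scores))
    data.frame(fold = f, n_test = length(test),
               precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]], ranking_loss = rl)
  })
  folds_df <- do.call(rbind, rows)
  means <- colMeans(folds_df[, c("precision", "recall", "f1", "ranking_loss")])
  list(folds = folds_df, mean = means, assignments = folds)
}
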