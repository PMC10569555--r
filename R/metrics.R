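# Predictive-power metrics: absolute/relative error for continuous
# outcomes, accuracy and AUROC for categorical ones, and the no-covariate
# empirical baselines.

#' Mean absolute and relative prediction error
#'
#' `abs = mean(|y - yhat|)`; `rel = mean(|(y - yhat) / y|)`, which is
#' undefined (`NA`) as soon as any observed outcome is 0 -- zero outcomes
#' are flagged rather than silently dropped.
#'
#' @param y observed outcomes.
#' @param yhat predictions.
#' @return list with `abs` and `rel`.
#' @export
abs_rel_error <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1L)
  d <- abs(y - yhat)
  list(abs = mean(d),
       rel = if (any(y == 0)) NA_real_ else mean(d / abs(y)))
}

#' Classification accuracy
#'
#' @param y observed category codes.
#' @param yhat predicted codes.
#' @return fraction of exact matches.
#' @export
accuracy <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1L)
  mean(y == yhat)
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' `AUROC = (sum of positive-class ranks - n1(n1+1)/2) / (n1 * n0)` with
#' midranks, so tied scores receive half credit.  Undefined (`NA`) when the
#' test set contains a single class.
#'
#' @param y binary codes (0/1; code 1 is the positive class).
#' @param scores predicted scores for code 1.
#' @return AUROC in `[0, 1]`, or `NA`.
#' @export
auroc <- function(y, scores) {
  stopifnot(length(y) == length(scores))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical (no-covariate) baseline prediction
#'
#' The most straightforward prediction: for continuous outcomes the
#' training-set mean, scored by absolute/relative error on the test set; for
#' categorical outcomes the constant code 0 (the most frequent category in
#' the full data by construction), scored by accuracy.  Not defined for the
#' AUROC objective, where no empirical entry is reported.
#'
#' @param train_y encoded training outcomes.
#' @param test_y encoded test outcomes.
#' @param mode `"linear"`, `"binary"` or `"multin"`.
#' @return for linear: list with `abs`, `rel`; otherwise list with `acc`.
#' @export
empirical_baseline <- function(train_y, test_y, mode) {
  stopifnot(length(train_y) >= 1L, length(test_y) >= 1L)
  if (mode == "linear") {
    abs_rel_error(test_y, rep(mean(train_y), length(test_y)))
  } else {
    list(acc = accuracy(test_y, rep(0L, length(test_y))))
  }
}
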