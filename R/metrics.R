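#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives of 0/1 predictions against
#' 0/1 truth, positive class being 1.
#'
#' @param predictions integer 0/1 vector.
#' @param truth integer 0/1 vector of the same length.
#' @return an object of class `confusion_counts` with fields `n_tp`, `n_tn`,
#'   `n_fp`, `n_fn`.
#' @examples
#' confusion(c(1, 0), c(1, 0))
#' @export
confusion <- function(predictions, truth) {
  predictions <- as.integer(predictions)
  truth <- as.integer(unclass(truth))
  if (length(predictions) != length(truth))
    stopf("length mismatch: %d predictions vs %d truths",
          length(predictions), length(truth))
  if (length(truth) < 1L) stopf("need at least one sample")
  if (!all(predictions %in% 0:1) || !all(truth %in% 0:1))
    stopf("predictions and truth must be 0/1 vectors")
  structure(list(n_tp = sum(predictions == 1L & truth == 1L),
                 n_tn = sum(predictions == 0L & truth == 0L),
                 n_fp = sum(predictions == 1L & truth == 0L),
                 n_fn = sum(predictions == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Assemble confusion counts directly
#'
#' @param n_tp,n_tn,n_fp,n_fn non-negative counts, at least one positive.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(n_tp, n_tn, n_fp, n_fn) {
  v <- c(n_tp, n_tn, n_fp, n_fn)
  if (anyNA(v) || any(v < 0) || sum(v) < 1) stopf("counts must be >= 0 with total >= 1")
  structure(list(n_tp = n_tp, n_tn = n_tn, n_fp = n_fp, n_fn = n_fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$n_tp, x$n_tn, x$n_fp, x$n_fn))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))`, the correlation
#' between observed and predicted binary labels.  When the denominator is 0
#' (any marginal empty), the coefficient is defined to be exactly 0.
#' Products are taken in double precision so large counts cannot overflow.
#'
#' @param c a `confusion_counts` object.
#' @return MCC in `[-1, 1]`.
#' @examples
#' mcc(confusion_counts(5, 5, 0, 0))   # 1
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- as.numeric(c$n_tp); tn <- as.numeric(c$n_tn)
  fp <- as.numeric(c$n_fp); fn <- as.numeric(c$n_fn)
  den <- (tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Standardized fitness
#'
#' Maps MCC affinely onto `[0, 1]`: `(1 + MCC) / 2`, higher is better and 1
#' is a perfect classifier.  This is the fitness maximized by [evolve()].
#'
#' @param mcc_value a value in `[-1, 1]`.
#' @return fitness in `[0, 1]`.
#' @export
standardized_fitness <- function(mcc_value) {
  if (!is.numeric(mcc_value) || anyNA(mcc_value) ||
      any(mcc_value < -1 - 1e-12) || any(mcc_value > 1 + 1e-12))
    stopf("MCC must lie in [-1, 1]")
  (1 + mcc_value) / 2
}

#' Training-set accuracy (MCC scale)
#'
#' The training performance measure is `MCC * 100`.  Note this is a
#' correlation on a percent scale, not a percent-correct: it can be
#' negative, and 0 means chance-level.  See [percent_correct()] for the
#' conventional fraction-correct measure.
#'
#' @param c a `confusion_counts` object.
#' @return `mcc(c) * 100`.
#' @export
training_accuracy <- function(c) 100 * mcc(c)

#' Test-set (balanced) accuracy
#'
#' The test performance measure: the mean of sensitivity and specificity,
#' `50 * (TP/(TP+FN) + TN/(TN+FP))`, on a percent scale.  Both classes must
#' be present in the evaluated set — use stratified folds (see
#' [stratified_folds()]) to guarantee this.
#'
#' @param c a `confusion_counts` object.
#' @return balanced accuracy in percent.
#' @export
test_accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  pos <- c$n_tp + c$n_fn
  neg <- c$n_tn + c$n_fp
  if (pos == 0 || neg == 0)
    stopf("balanced accuracy undefined: a class is absent from the evaluation set; use stratified folds")
  50 * (c$n_tp / pos + c$n_tn / neg)
}

#' Percent of samples classified correctly
#'
#' Conventional accuracy, `100 * (TP + TN) / total`; provided as a sanity
#' check alongside [training_accuracy()], which is on the MCC scale.
#'
#' @param c a `confusion_counts` object.
#' @return percent correct in `[0, 100]`.
#' @export
percent_correct <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  100 * (c$n_tp + c$n_tn) / (c$n_tp + c$n_tn + c$n_fp + c$n_fn)
}
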