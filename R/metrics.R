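#' Area under the ROC curve by the Mann-Whitney estimator
#'
#' Computes AUC as the probability that a random positive case scores above
#' a random negative case, counting tied pairs as one half: with midranks
#' \eqn{r_i} of the pooled scores, \eqn{AUC = (\bar r_+ - (n_+ + 1)/2) /
#' n_-}. Equivalent to pair counting (concordant + tied/2 over all
#' positive-negative pairs) and to trapezoidal integration of the empirical
#' ROC curve.
#'
#' @param scores Numeric vector of positive-class scores.
#' @param labels Outcome labels (character or factor); `positive` names the
#'   positive class.
#' @param positive Positive class label, default `"seizure_free"`.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4), c("seizure_free", "seizure_free",
#'                             "improvement_only"))
roc_auc <- function(scores, labels, positive = "seizure_free") {
  pos <- as.character(labels) == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: one class absent", call. = FALSE)
  }
  r <- rank(scores)  # midranks
  (mean(r[pos]) - (n1 + 1) / 2) / n0
}

#' F-measure from a binary confusion
#'
#' \eqn{F_1 = 2PR/(P+R)} with precision \eqn{P = TP/(TP+FP)} and recall
#' \eqn{R = TP/(TP+FN)}; the seizure-free class is treated as positive.
#' Returns 0 when there are no true positives (the zero-recall convention).
#'
#' @param confusion Named numeric vector or list with elements `TP`, `FP`,
#'   `TN`, `FN`.
#' @return F-measure in `[0, 1]`.
#' @export
#' @examples
#' f_measure(c(TP = 14, FP = 2, TN = 3, FN = 0))
f_measure <- function(confusion) {
  cf <- unlist(confusion)[c("TP", "FP", "TN", "FN")]
  stopifnot(all(!is.na(cf)), all(cf >= 0))
  if (sum(cf) == 0) stop("empty confusion", call. = FALSE)
  if (cf[["TP"]] == 0) return(0)
  p <- cf[["TP"]] / (cf[["TP"]] + cf[["FP"]])
  r <- cf[["TP"]] / (cf[["TP"]] + cf[["FN"]])
  2 * p * r / (p + r)
}

# TP/FP/TN/FN with seizure_free positive
confusion_counts <- function(predicted, truth) {
  pos_pred <- predicted == "seizure_free"
  pos_true <- truth == "seizure_free"
  c(TP = sum(pos_pred & pos_true), FP = sum(pos_pred & !pos_true),
    TN = sum(!pos_pred & !pos_true), FN = sum(!pos_pred & pos_true))
}
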