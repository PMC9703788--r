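#' Sensitivity and specificity of binary predictions
#'
#' Sensitivity is the fraction of positive-class subjects (the patients
#' under test) correctly classified, specificity the fraction of
#' negative-class subjects correctly classified; both are returned as
#' percentages.
#'
#' @param predicted character/factor vector of predicted labels.
#' @param labels true labels, same length.
#' @param positive the label treated as the positive class.
#' @return named numeric vector `c(sensitivity =, specificity =)` in
#'   percent.
#' @export
confusion_rates <- function(predicted, labels, positive) {
  predicted <- as.character(predicted)
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present in labels")
  c(sensitivity = 100 * mean(predicted[pos] == positive),
    specificity = 100 * mean(predicted[!pos] != positive))
}

#' Balanced accuracy
#'
#' The arithmetic mean of sensitivity and specificity, the accuracy
#' definition used throughout the classification stage (robust to the small
#' class-size imbalance between patient groups).
#'
#' @param sensitivity,specificity percentages in `[0, 100]`.
#' @return balanced accuracy in percent.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100)
  (sensitivity + specificity) / 2
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' Area under the ROC curve computed from ranks: with `P` positives and `Q`
#' negatives and ranks taken over the pooled scores ascending (ties get the
#' mean rank),
#' `AUC = (sum of positive ranks - P(P+1)/2) / (P * Q)`,
#' which equals the Mann-Whitney U statistic divided by `P * Q`.
#'
#' @param scores numeric decision scores, larger favouring the positive
#'   class.
#' @param labels true labels.
#' @param positive the positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels, positive) {
  labels <- as.character(labels)
  pos <- labels == positive
  P <- sum(pos)
  Q <- sum(!pos)
  if (P == 0L || Q == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - P * (P + 1) / 2) / (P * Q)
}

#' ROC curve by threshold sweep
#'
#' Standard sweep over the unique scores in decreasing order: each threshold
#' classifies scores `>=` it as positive, giving one (FPR, TPR) point; the
#' curve starts at (0, 0) and ends at (1, 1) and its trapezoidal area equals
#' [auc_rank()] to numerical precision.
#'
#' @inheritParams auc_rank
#' @return data frame with columns `threshold`, `fpr`, `tpr` (the first row
#'   is the (0,0) corner with threshold `Inf`).
#' @export
roc_curve <- function(scores, labels, positive) {
  labels <- as.character(labels)
  pos <- labels == positive
  P <- sum(pos)
  Q <- sum(!pos)
  if (P == 0L || Q == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / P, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / Q, 0)
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc data frame from [roc_curve()].
#' @return area in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}
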