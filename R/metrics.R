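# Binary classification metrics: sensitivity, specificity, accuracy,
# Matthews correlation coefficient, and the ROC AUC as the Mann-Whitney
# rank statistic (ties contribute 1/2), which equals the trapezoidal area
# under the empirical ROC curve.

#' Confusion counts from predictions and truth
#'
#' @param predicted 0/1 vector of predicted classes.
#' @param truth 0/1 vector of true labels.
#' @return list with integer elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth),
            all(predicted %in% 0:1), all(truth %in% 0:1))
  list(TP = sum(predicted == 1 & truth == 1),
       TN = sum(predicted == 0 & truth == 0),
       FP = sum(predicted == 1 & truth == 0),
       FN = sum(predicted == 0 & truth == 1))
}

#' Threshold metrics from confusion counts
#'
#' SN = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/total and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is returned as `NA` with a warning
#' (small folds can lack a class); callers exclude `NA`s from averages.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN` (see [confusion_counts()]).
#' @return named numeric vector `SN`, `SP`, `ACC`, `MCC`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("all-zero confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NA_real_ }
    else num / den
  }
  mcc_den <- sqrt(prod(c(TP + FN, TP + FP, TN + FP, TN + FN)))
  c(SN = safe_div(TP, TP + FN, "SN"),
    SP = safe_div(TN, TN + FP, "SP"),
    ACC = (TP + TN) / total,
    MCC = safe_div(TP * TN - FP * FN, mcc_den, "MCC"))
}

#' ROC AUC via the rank (Mann-Whitney) statistic
#'
#' Probability that a random positive scores above a random negative, with
#' tied scores counted 1/2; identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 true labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
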