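# Binary-classification metric suite: sensitivity, specificity,
# precision, accuracy, Matthews correlation, and threshold-sweep ROC/AUC.

#' Metrics from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Named numeric vector `SEN`, `SPE`, `PRE`, `ACC`, `MCC`.
#'   A metric whose denominator is zero is reported as `NA`, never
#'   coerced to 0.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(SEN = safe(tp, tp + fn),
    SPE = safe(tn, fp + tn),
    PRE = safe(tp, tp + fp),
    ACC = safe(tp + tn, tp + tn + fp + fn),
    MCC = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den)
}

#' Confusion counts of scores against labels at a threshold
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Scores `>= threshold` predict the positive class.
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  c(tp = sum(pred == 1L & labels == 1L),
    fp = sum(pred == 1L & labels == 0L),
    tn = sum(pred == 0L & labels == 0L),
    fn = sum(pred == 0L & labels == 1L))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold and integrates the ROC by
#' the trapezoid rule; the result equals the normalized Mann-Whitney U
#' statistic (ties counted half).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `roc` (data frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # cut after each run of tied scores
  last_of_run <- which(c(s[-1] != s[-length(s)], TRUE))
  tpr <- c(0, cumsum(l)[last_of_run] / n_pos)
  fpr <- c(0, cumsum(1 - l)[last_of_run] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
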