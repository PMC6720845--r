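# Confusion-matrix arithmetic: Acc, SN, SPE, Pre, F1, MCC (reported as
# percentages), the fn/fp rates used for threshold balancing, and ROC/AUC.

#' Confusion counts
#'
#' Either supply the four counts directly, or `truth`/`predicted` 0/1 vectors
#' from which they are tallied (positive class = 1).
#'
#' @param tp,tn,fp,fn nonnegative integer counts
#' @param truth,predicted optional 0/1 vectors
#' @return object of class `confusion_counts`
#' @export
confusion_counts <- function(tp = NULL, tn = NULL, fp = NULL, fn = NULL,
                             truth = NULL, predicted = NULL) {
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(predicted),
              all(truth %in% 0:1), all(predicted %in% 0:1))
    tp <- sum(truth == 1 & predicted == 1)
    tn <- sum(truth == 0 & predicted == 0)
    fp <- sum(truth == 0 & predicted == 1)
    fn <- sum(truth == 1 & predicted == 0)
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) < 1) stop("empty confusion matrix")
  structure(as.list(counts), class = "confusion_counts")
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator")
    return(NA_real_)
  }
  num / den
}

#' All confusion-matrix metrics, as percentages
#'
#' Exact arithmetic of the standard definitions: `Acc = (TP+TN)/total`,
#' `SN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `Pre = TP/(TP+FP)`,
#' `F1 = 2TP/(2TP+FP+FN)`,
#' `MCC = (TP*TN - FP*FN)/sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' A metric with a zero denominator is reported as `NA` with a warning, not
#' as 0. Values are full precision; round only for presentation.
#'
#' @param counts a [confusion_counts()] object
#' @return object of class `metric_report`: list with `acc`, `sn`, `spe`,
#'   `pre`, `f1`, `mcc`, `fn_rate`, `fp_rate` (all on the 0-100 scale;
#'   `mcc` in [-100, 100])
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  mcc_den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined: zero denominator")
    NA_real_
  } else (tp * tn - fp * fn) / mcc_den
  structure(list(
    acc = 100 * .safe_ratio(tp + tn, tp + fp + tn + fn, "Acc"),
    sn  = 100 * .safe_ratio(tp, tp + fn, "SN"),
    spe = 100 * .safe_ratio(tn, tn + fp, "SPE"),
    pre = 100 * .safe_ratio(tp, tp + fp, "Pre"),
    f1  = 100 * .safe_ratio(2 * tp, 2 * tp + fp + fn, "F1"),
    mcc = 100 * mcc,
    fn_rate = 100 * .safe_ratio(fn, fn + tp, "fn rate"),
    fp_rate = 100 * .safe_ratio(fp, fp + tn, "fp rate")
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(paste(sprintf("%s=%.2f%%", toupper(names(x)), unlist(x)),
            collapse = "  "), "\n")
  invisible(x)
}

#' False-negative and false-positive rates
#'
#' `fn = FN/(FN+TP)`, `fp = FP/(FP+TN)`; the complements of sensitivity and
#' specificity. Returned on the 0-1 scale (multiply by 100 for percent).
#'
#' @inheritParams compute_metrics
#' @return named vector `c(fn_rate, fp_rate)`
#' @export
fn_fp_rates <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  c(fn_rate = .safe_ratio(counts$fn, counts$fn + counts$tp, "fn rate"),
    fp_rate = .safe_ratio(counts$fp, counts$fp + counts$tn, "fp rate"))
}

#' ROC curve and AUC
#'
#' Trapezoidal AUC over all distinct score thresholds, equivalent to the
#' Mann-Whitney statistic with midrank handling of ties (a tied
#' positive/negative pair contributes 1/2).
#'
#' @param scores numeric scores, higher = more positive
#' @param labels 0/1 vector, both classes present
#' @return list with `auc` in [0, 1] and `roc` (data frame of
#'   threshold/fpr/tpr points, threshold descending)
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  # Mann-Whitney via midranks
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # ROC points: sweep thresholds downwards through distinct scores
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y); cum_fp <- cumsum(1L - y)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tie group
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, cum_fp[last] / n_neg),
                    tpr = c(0, cum_tp[last] / n_pos))
  list(auc = auc, roc = roc)
}
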