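# Classification metrics: confusion-matrix summaries and threshold-free
# curve areas.

#' Confusion-matrix performance metrics
#'
#' Accuracy, precision, recall (sensitivity), specificity and the Matthews
#' correlation coefficient from true/false positive/negative counts.
#' A metric whose denominator is zero is reported as `NA` (an undefined
#' marker, not an error); the MCC with a zero denominator is reported as 0
#' and flagged in the `mcc_undefined` field, the usual convention that keeps
#' fold reports aggregatable.
#'
#' @param tp,tn,fp,fn non-negative counts; alternatively pass a single list
#'   or named vector with those fields as `tp`.
#' @return named list with accuracy, precision, recall, specificity, mcc
#'   and the logical `mcc_undefined`.
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp) || (is.numeric(tp) && length(tp) == 4 && !is.null(names(tp)))) {
    counts <- tp
    tn <- counts[["tn"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
    tp <- counts[["tp"]]
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc_undefined <- mcc_den == 0
  list(
    accuracy = div(tp + tn, tp + tn + fp + fn),
    precision = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    # clamp against floating-point overshoot just outside [-1, 1]
    mcc = if (mcc_undefined) 0 else
      min(1, max(-1, (tp * tn - fp * fn) / mcc_den)),
    mcc_undefined = mcc_undefined
  )
}

#' Areas under the ROC and precision-recall curves
#'
#' AUCROC is computed with the rank statistic (Mann-Whitney form; tied
#' scores count one half). AUCPR integrates precision over recall steps:
#' thresholds sweep the distinct scores in descending order and each recall
#' increment contributes the precision at that threshold.
#'
#' @param scores numeric scores, higher = more active.
#' @param labels logical (or coercible) true class, `TRUE` = active.
#' @return list with `aucroc` and `aucpr`.
#' @export
roc_pr_areas <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # mid-ranks handle ties at one half
  aucroc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  ctp <- cumsum(y)[grp_last]
  cn <- grp_last
  prec <- ctp / cn
  rec <- ctp / n1
  prev_rec <- c(0, rec[-length(rec)])
  aucpr <- sum((rec - prev_rec) * prec)
  list(aucroc = aucroc, aucpr = aucpr)
}
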