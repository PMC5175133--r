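#' Confusion matrix for a binary classifier
#'
#' Conventions: `tp` = positives correctly predicted, `fn` = positives missed,
#' `fp` = negatives predicted positive, `tn` = negatives correctly predicted.
#'
#' @param tp,fn,fp,tn Non-negative counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(vapply(v, is_count1, logical(1))))
  if (sum(v) < 1) data_error("confusion matrix total must be >= 1")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("true positive", "true negative"),
                              c("pred positive", "pred negative")))
  print(m)
  invisible(x)
}

#' Classifier evaluation metrics
#'
#' The four standard confusion-matrix summaries:
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with MCC
#' defined as 0 when any factor under the root is 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A number.
#' @export
sensitivity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) data_error("sensitivity undefined: no positives")
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tn + cm$fp == 0) data_error("specificity undefined: no negatives")
  cm$tn / (cm$tn + cm$fp)
}

#' @rdname sensitivity
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn)
}

#' @rdname sensitivity
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Summary of all four metrics, as fractions and percentages
#'
#' @param cm A [confusion_matrix()].
#' @return List with `fraction` (named vector, Sn/Sp/Acc/MCC) and `percent`
#'   (Sn/Sp/Acc rounded to one decimal, as the field's tables print them;
#'   MCC is left as a fraction).
#' @export
metrics_summary <- function(cm) {
  f <- c(Sn = sensitivity(cm), Sp = specificity(cm), Acc = accuracy(cm), MCC = mcc(cm))
  list(fraction = f,
       percent = c(Sn = round(100 * f[["Sn"]], 1),
                   Sp = round(100 * f[["Sp"]], 1),
                   Acc = round(100 * f[["Acc"]], 1),
                   MCC = round(f[["MCC"]], 3)))
}

#' Area under the ROC curve
#'
#' Computed by the rank-sum (Mann-Whitney) identity:
#' `AUC = P(score_pos > score_neg) + 0.5 * P(tie)`, using midranks so ties
#' are handled exactly.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels; `positive` marks the positive class.
#' @param positive Value of `labels` treated as positive; default `1` or, if
#'   absent, the second sorted unique label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  if (is.null(positive))
    positive <- if (1 %in% labels) 1 else sort(unique(labels))[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) data_error("both classes must be present")
  r <- rank(scores)                 # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
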