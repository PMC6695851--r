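#' Confusion matrix for a two-class screen
#'
#' Counts follow the clinical layout: rows are the predicted class, columns
#' the ground truth, with "positive" the class of clinical interest.
#'
#' @param tp,fp,fn,tn non-negative counts
#' @return object of class `confusion_matrix`
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_domain("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param truth,pred label vectors ("positive"/"negative" or +1/-1)
#' @export
confusion_from_labels <- function(truth, pred) {
  t1 <- as_pm1(truth); p1 <- as_pm1(pred)
  if (length(t1) != length(p1)) stop_domain("label length mismatch")
  confusion_matrix(tp = sum(p1 == 1 & t1 == 1),
                   fp = sum(p1 == 1 & t1 == -1),
                   fn = sum(p1 == -1 & t1 == 1),
                   tn = sum(p1 == -1 & t1 == -1))
}

#' @export
`+.confusion_matrix` <- function(e1, e2) {
  confusion_matrix(e1$tp + e2$tp, e1$fp + e2$fp, e1$fn + e2$fn, e1$tn + e2$tn)
}

#' Derived metrics of a confusion matrix
#'
#' Accuracy, sensitivity (true-positive rate), specificity, type I error
#' (false-positive rate) and type II error (false-negative rate, the
#' fraction of truly positive subjects classified negative), as fractions,
#' plus each cell as a percentage of the total. Undefined ratios (empty
#' denominator) are reported as `NA`, not 0.
#'
#' @param cm a [confusion_matrix()]
#' @return list with `accuracy`, `sensitivity`, `specificity`,
#'   `type_I_error`, `type_II_error` (fractions), `cell_pct` (percent of
#'   total per cell) and `total`
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop_domain("empty confusion matrix")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = (cm$tp + cm$tn) / total,
       sensitivity = safe(cm$tp, cm$tp + cm$fn),
       specificity = safe(cm$tn, cm$tn + cm$fp),
       type_I_error = safe(cm$fp, cm$fp + cm$tn),
       type_II_error = safe(cm$fn, cm$tp + cm$fn),
       cell_pct = c(tp = 100 * cm$tp / total, fp = 100 * cm$fp / total,
                    fn = 100 * cm$fn / total, tn = 100 * cm$tn / total),
       total = total)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- confusion_metrics(x)
  pct <- function(v) ifelse(is.na(v), "-", sprintf("%.2f%%", 100 * v))
  cat(sprintf("          truth+  truth-\n"))
  cat(sprintf("pred+  TP %5d  FP %5d\n", x$tp, x$fp))
  cat(sprintf("pred-  FN %5d  TN %5d\n", x$fn, x$tn))
  cat(sprintf("accuracy %s  sensitivity %s  specificity %s\n",
              pct(m$accuracy), pct(m$sensitivity), pct(m$specificity)))
  cat(sprintf("type I error %s  type II error %s  (n = %d)\n",
              pct(m$type_I_error), pct(m$type_II_error), m$total))
  invisible(x)
}
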