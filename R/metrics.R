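#' Confusion counts for binary lesion classification
#'
#' Positive class is malignant (label 1) throughout the package.
#'
#' @param truth,pred Equal-length vectors over `{0, 1}`.
#' @return A list of class `confusion_counts` with integer `TP`, `TN`,
#'   `FP`, `FN`.
#' @examples
#' confusion(c(1, 0), c(1, 0))
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("`truth` and `pred` must have equal length", call. = FALSE)
  if (length(truth) < 1) stop("need at least one sample", call. = FALSE)
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  confusion_counts(TP = sum(truth == 1 & pred == 1),
                   TN = sum(truth == 0 & pred == 0),
                   FP = sum(truth == 0 & pred == 1),
                   FN = sum(truth == 1 & pred == 0))
}

#' @rdname confusion
#' @param TP,TN,FP,FN Nonnegative integer counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- list(TP = TP, TN = TN, FP = FP, FN = FN)
  ok <- vapply(counts, function(v)
    length(v) == 1 && is.finite(v) && v >= 0 && v == round(v), logical(1))
  if (!all(ok))
    stop("counts must be nonnegative integers", call. = FALSE)
  structure(lapply(counts, as.integer), class = "confusion_counts")
}

#' Precision, recall, specificity, accuracy and F-measure
#'
#' Standard confusion-matrix metrics with malignant as the positive class:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/total`, and the F-measure as the harmonic mean of
#' precision and recall. Any 0/0 ratio is defined as 0 with a warning.
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric vector of the five metrics, each in \[0, 1\].
#' @examples
#' metric_suite(confusion_counts(8, 9, 4, 6))["accuracy"]  # 17/27
#' @export
metric_suite <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total < 1) stop("confusion counts sum to zero", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is 0/0; defining it as 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- ratio(counts$TP, counts$TP + counts$FP, "precision")
  recall <- ratio(counts$TP, counts$TP + counts$FN, "recall")
  specificity <- ratio(counts$TN, counts$TN + counts$FP, "specificity")
  accuracy <- (counts$TP + counts$TN) / total
  f_measure <- ratio(2 * precision * recall, precision + recall, "f_measure")
  c(precision = precision, recall = recall, specificity = specificity,
    accuracy = accuracy, f_measure = f_measure)
}

#' Round metrics for report display
#'
#' Half-away-from-zero rounding to `digits` decimals (so 0.825 displays as
#' 0.83, where banker's rounding would give 0.82), matching how clinical
#' classification tables are conventionally printed.
#'
#' @param x Numeric vector.
#' @param digits Decimal places. Default 2.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts TP=%d TN=%d FP=%d FN=%d>\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}
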