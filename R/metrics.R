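#' Binary confusion matrix
#'
#' Counts true/false positives and negatives of a binary prediction
#' against ground truth, with an explicit positive label.
#'
#' @param truth,pred Equal-length label vectors.
#' @param positive The label counted as positive.
#' @return Object of class `confusion`: list with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(truth, pred, positive) {
  if (length(truth) != length(pred))
    stop("truth and pred differ in length (", length(truth), " vs ",
         length(pred), ")")
  t_pos <- truth == positive
  p_pos <- pred == positive
  confusion_counts(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
                   TN = sum(!t_pos & !p_pos), FN = sum(t_pos & !p_pos))
}

#' @rdname confusion
#' @param TP,FP,TN,FN Non-negative integer counts (at least one positive
#'   total), for building a confusion matrix directly from published
#'   counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  cm <- list(TP = as.integer(TP), FP = as.integer(FP),
             TN = as.integer(TN), FN = as.integer(FN))
  if (any(vapply(cm, `<`, TRUE, 0L))) stop("counts must be non-negative")
  if (sum(unlist(cm)) < 1L) stop("confusion matrix is empty")
  class(cm) <- "confusion"
  cm
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Figures of merit for a binary classifier
#'
#' The five standard merit figures of a binary confusion matrix:
#' \deqn{Accuracy = (TP+TN)/(TP+TN+FN+FP)}
#' \deqn{TPR = TP/(TP+FN)} \deqn{TNR = TN/(TN+FP)}
#' \deqn{F1 = 2TP/(2TP+FP+FN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' `tpr()` and `mcc()` follow the usual conventions: TPR/TNR raise an
#' error when their class is absent (denominator zero), while MCC
#' returns 0 whenever any factor under the radical is zero.
#'
#' @param cm A [confusion] object.
#' @return A single numeric value.
#' @name merit
NULL

#' @rdname merit
#' @export
accuracy <- function(cm) {
  with(cm, (TP + TN) / (TP + TN + FN + FP))
}

#' @rdname merit
#' @export
tpr <- function(cm) {
  if (cm$TP + cm$FN == 0L)
    stop("TPR undefined: no actual positives (TP + FN = 0)")
  cm$TP / (cm$TP + cm$FN)
}

#' @rdname merit
#' @export
tnr <- function(cm) {
  if (cm$TN + cm$FP == 0L)
    stop("TNR undefined: no actual negatives (TN + FP = 0)")
  cm$TN / (cm$TN + cm$FP)
}

#' @rdname merit
#' @export
f1 <- function(cm) {
  with(cm, 2 * TP / (2 * TP + FP + FN))
}

#' @rdname merit
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$TP); fp <- as.numeric(cm$FP)
  tn <- as.numeric(cm$TN); fn <- as.numeric(cm$FN)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

# One evaluation row in the merit-table layout; NA-safe for cells where
# a class is absent.
merit_row <- function(cm) {
  safe <- function(f) tryCatch(f(cm), error = function(e) NA_real_)
  c(accuracy = accuracy(cm), TPR = safe(tpr), TNR = safe(tnr),
    F1 = f1(cm), MCC = mcc(cm))
}
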