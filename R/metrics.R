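#' Confusion matrix (rows = predicted, columns = reference)
#'
#' @param y_true reference labels.
#' @param y_pred predicted labels, same length.
#' @param classes class vocabulary fixing row/column order.
#' @return integer matrix `[n_classes x n_classes]`.
#' @export
confusion <- function(y_true, y_pred, classes) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% classes) || !all(y_pred %in% classes))
    stop("label outside class vocabulary")
  tab <- table(factor(y_pred, levels = classes),
               factor(y_true, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(predicted = classes, reference = classes))
  m
}

#' Classification accuracy from a confusion matrix
#'
#' Trace over total. In the binary case this is the familiar
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm confusion matrix from [confusion()].
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Macro-averaged F1 score from a confusion matrix
#'
#' Per class, one-vs-rest precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)` give `F1 = 2 P R / (P + R)` (0 when `P + R = 0`); the
#' macro score is their unweighted mean over classes, which keeps rare
#' classes on an equal footing with common ones. Micro and weighted
#' averaging are available for comparison.
#'
#' @param cm confusion matrix, rows = predicted, columns = reference.
#' @param average `"macro"` (default), `"micro"` or `"weighted"`.
#' @return F1 in `[0, 1]`.
#' @export
macro_f1 <- function(cm, average = c("macro", "micro", "weighted")) {
  average <- match.arg(average)
  if (nrow(cm) < 2L) stop("need at least 2 classes")
  tp <- diag(cm)
  fp <- rowSums(cm) - tp  # predicted as class but wrong
  fn <- colSums(cm) - tp  # class missed
  if (average == "micro") {
    denom <- sum(tp) + (sum(fp) + sum(fn)) / 2
    return(if (denom == 0) 0 else sum(tp) / denom)
  }
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec  <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  if (average == "macro") mean(f1)
  else sum(f1 * colSums(cm)) / sum(cm)
}

#' Mean and 95% t-interval half-width of repeated metric values
#'
#' Repeated tests of a model yield a sequence of accuracies (or F1 scores);
#' the half-width `h = sem * t` summarises their dispersion, where `sem` is
#' the standard error `sd / sqrt(n)` (sample standard deviation, `n - 1`
#' denominator) and `t` the right-tail quantile of the t-distribution with
#' `n - 1` degrees of freedom at the chosen confidence level. With a single
#' value `h` is undefined and reported as 0 with a warning.
#'
#' @param values numeric vector of metric values.
#' @param confidence confidence level (default 0.95).
#' @return list with `mean` and `h`.
#' @export
mean_and_h <- function(values, confidence = 0.95) {
  n <- length(values)
  if (n == 0L) stop("empty input")
  m <- mean(values)
  if (n == 1L) {
    warning("half-width undefined for a single value; reporting 0")
    return(list(mean = m, h = 0))
  }
  sem <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  list(mean = m, h = sem * tq)
}
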