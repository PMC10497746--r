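#' Confusion counts
#'
#' @param TP,FP,FN,TN Nonnegative integer counts (true/false
#'   positives/negatives).
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, FP, FN, TN = 0L) {
  v <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(v < 0)) stop("confusion counts must be nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. A metric whose
#' denominator is zero is reported as 0 with its `undefined` flag set (rather
#' than NaN), which keeps downstream aggregation stable.
#'
#' @param counts A [confusion_counts()] (TN is not used).
#' @return List with `precision`, `recall`, `f1` and logical flags
#'   `undefined` (one per metric).
#' @examples
#' precision_recall_f1(confusion_counts(TP = 10, FP = 0, FN = 0))
#' @export
precision_recall_f1 <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  und <- c(precision = FALSE, recall = FALSE, f1 = FALSE)
  if (tp + fp > 0) p <- tp / (tp + fp) else { p <- 0; und["precision"] <- TRUE }
  if (tp + fn > 0) r <- tp / (tp + fn) else { r <- 0; und["recall"] <- TRUE }
  if (p + r > 0) f1 <- 2 * p * r / (p + r) else { f1 <- 0; und["f1"] <- TRUE }
  list(precision = p, recall = r, f1 = f1, undefined = und)
}

#' Average precision (area under the precision-recall curve)
#'
#' Detections are ranked by descending score; at every distinct score
#' threshold the precision and recall of the detections at or above it are
#' computed, and AP is the all-points sum `sum((R_i - R_{i-1}) * P_i)` — the
#' exact area of the step curve, not the 11-point approximation. Tied scores
#' enter together.
#'
#' @param scores Numeric detection scores.
#' @param truth Logical (or 0/1) flags: is the detection a true positive?
#' @param n_positives Total number of ground-truth positives; defaults to
#'   `sum(truth)`. Must be `>= 1`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, truth, n_positives = NULL) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  if (is.null(n_positives)) n_positives <- sum(truth)
  if (n_positives < 1) stop("average precision needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  sc <- scores[o]; tr <- truth[o]
  cut_ends <- which(c(diff(sc) != 0, TRUE))  # last index of each tied group
  tp <- cumsum(tr)[cut_ends]
  np <- cut_ends
  prec <- tp / np
  rec <- tp / n_positives
  sum(diff(c(0, rec)) * prec)
}

#' Mean average precision over classes
#'
#' @param per_class_ap Nonempty vector of per-class AP values.
#' @return Their arithmetic mean.
#' @export
mean_average_precision <- function(per_class_ap) {
  if (length(per_class_ap) == 0L) stop("empty AP vector")
  mean(per_class_ap)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSR/SST` with `SSR = sum((y - yhat)^2)` (residual sum of
#' squares) and `SST = sum((y - mean(y))^2)` (total sum of squares).
#'
#' @param actual Observed values (length >= 2, not constant).
#' @param predicted Predicted values, same length.
#' @return R-squared (<= 1; negative when predictions are worse than the
#'   mean).
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 2L) stop("need at least two observations")
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("R-squared undefined: `actual` is constant")
  1 - sum((actual - predicted)^2) / sst
}

#' Root-mean-square error
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`.
#'
#' @param actual,predicted Paired numeric vectors of equal length.
#' @return RMSE (same units as the inputs).
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) == 0L) stop("empty input")
  sqrt(mean((actual - predicted)^2))
}
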