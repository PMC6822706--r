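# Pixelwise segmentation accuracy against ground-truth binary images.

#' Pixelwise confusion counts between a segmentation and its ground truth
#'
#' @param pred Logical matrix, the predicted segmentation.
#' @param truth Logical matrix of the same shape, the ground truth.
#' @return A list of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn`; the four counts sum to the pixel count of the image.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- check_binary(pred)
  truth <- check_binary(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and ground truth must have the same shape")
  structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                 fn = sum(!pred & truth), tn = sum(!pred & !truth)),
            class = "confusion_counts")
}

#' Segmentation accuracy metrics from confusion counts
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, F-measure (harmonic mean of
#' precision and recall) and the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. Any metric whose
#' denominator is zero is reported as 0 (a documented convention that keeps
#' batch tables numeric; such rows are degenerate segmentations).
#'
#' @param counts A `confusion_counts` object, or a list/vector with fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @return Named numeric vector `precision`, `recall`, `f_measure`, `mcc`.
#' @examples
#' accuracy_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))
#' @export
accuracy_metrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  fn <- as.numeric(counts[["fn"]]); tn <- as.numeric(counts[["tn"]])
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be >= 0")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_measure <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  c(precision = precision, recall = recall, f_measure = f_measure, mcc = mcc)
}

#' Batch segmentation evaluation with a trailing average row
#'
#' Computes the four accuracy metrics for each prediction/truth pair and
#' appends a row labeled `Average` holding the column means, mirroring the
#' conventional presentation of segmentation benchmarks.
#'
#' @param preds List of logical matrices (predictions).
#' @param truths List of logical matrices (ground truths), same length and
#'   shapes.
#' @param names Optional character vector of image names; defaults to
#'   `image_1`, `image_2`, ...
#' @return Data frame with columns `image`, `precision`, `recall`,
#'   `f_measure`, `mcc`; the last row is the average.
#' @export
evaluate_segmentation <- function(preds, truths, names = NULL) {
  stopifnot(is.list(preds), is.list(truths), length(preds) == length(truths))
  if (length(preds) == 0) stop("no images to evaluate")
  if (is.null(names)) names <- paste0("image_", seq_along(preds))
  rows <- t(vapply(seq_along(preds), function(i)
    accuracy_metrics(confusion_counts(preds[[i]], truths[[i]])),
    numeric(4)))
  out <- data.frame(image = names, rows, stringsAsFactors = FALSE)
  avg <- data.frame(image = "Average", t(colMeans(rows)))
  rbind(out, avg)
}
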