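# Losses and confusion-matrix metrics.
#
# Soft Dice is computed globally over the raster with smoothing 1e-6;
# binary cross-entropy clamps probabilities at 1e-7. The combined training
# loss is (1 - alpha) * BCE + alpha * DiceLoss.

BCE_CLAMP <- 1e-7
DICE_SMOOTH <- 1e-6

checkShapes <- function(p, y) {
  if (!identical(dim(p), dim(y)) || length(p) != length(y))
    validationError(sprintf(
      "shape mismatch: prediction (%s) vs reference (%s)",
      paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x"),
      paste(if (is.null(dim(y))) length(y) else dim(y), collapse = "x")))
}

#' Binary cross-entropy loss
#'
#' Mean pixelwise binary cross-entropy
#' \eqn{-\frac1N \sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]} with
#' probabilities clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p probability raster (any shape).
#' @param y binary reference of the same shape.
#' @return non-negative scalar.
#' @examples
#' bceLoss(matrix(0.5, 4, 4), matrix(c(0, 1), 4, 4))  # log(2)
#' @export
bceLoss <- function(p, y) {
  checkShapes(p, y)
  pc <- pmin(pmax(p, BCE_CLAMP), 1 - BCE_CLAMP)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Soft Dice loss
#'
#' \eqn{1 - (2\sum p y + \epsilon) / (\sum p + \sum y + \epsilon)} with
#' \eqn{\epsilon = 10^{-6}}, computed over the whole raster. Zero for a
#' perfect binary prediction, one for disjoint non-empty masks.
#'
#' @inheritParams bceLoss
#' @return scalar in [0, 1].
#' @export
diceLoss <- function(p, y) {
  checkShapes(p, y)
  1 - (2 * sum(p * y) + DICE_SMOOTH) / (sum(p) + sum(y) + DICE_SMOOTH)
}

#' Combined BCE + Dice loss
#'
#' `(1 - alpha) * bceLoss(p, y) + alpha * diceLoss(p, y)`. The Dice term
#' counters foreground/background imbalance; the BCE term keeps per-pixel
#' gradients well-scaled.
#'
#' @inheritParams bceLoss
#' @param alpha weight of the Dice term, in [0, 1].
#' @return non-negative scalar.
#' @export
combinedLoss <- function(p, y, alpha = 0.5) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    configError(sprintf("alpha must lie in [0, 1]; got %s", alpha))
  (1 - alpha) * bceLoss(p, y) + alpha * diceLoss(p, y)
}

#' Threshold probabilities to a binary raster
#'
#' Values strictly greater than the threshold map to 1; values less than or
#' equal to it map to 0 (ties go to background).
#'
#' @param p probability raster.
#' @param threshold scalar threshold (default 0.5).
#' @return binary raster of the same shape.
#' @examples
#' binarize(c(0.4, 0.5, 0.6))  # 0 0 1
#' @export
binarize <- function(p, threshold = 0.5) {
  (p > threshold) * 1
}

#' Pixel confusion counts between binary rasters
#'
#' @param pred binary prediction raster.
#' @param truth binary reference raster of the same shape.
#' @return A [ConfusionCounts-class] with `tp + fp + fn + tn` equal to the
#'   number of pixels.
#' @examples
#' counts(confusionCounts(matrix(c(1, 0, 0, 1), 2), matrix(c(1, 1, 0, 0), 2)))
#' @export
confusionCounts <- function(pred, truth) {
  checkShapes(pred, truth)
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    validationError("confusionCounts requires strictly binary rasters")
  tp <- as.numeric(sum(pred == 1 & truth == 1))
  fp <- as.numeric(sum(pred == 1 & truth == 0))
  fn <- as.numeric(sum(pred == 0 & truth == 1))
  tn <- as.numeric(sum(pred == 0 & truth == 0))
  new("ConfusionCounts", tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#' @param c a [ConfusionCounts-class].
#' @return scalar in [0, 1].
#' @export
accuracyScore <- function(c) {
  tot <- c@tp + c@fp + c@fn + c@tn
  if (tot <= 0) undefinedMetricError("accuracy undefined on an empty raster")
  (c@tp + c@tn) / tot
}

#' Dice score (hard overlap)
#'
#' `2 TP / (FN + 2 TP + FP)`; undefined when both masks are empty.
#' @inheritParams accuracyScore
#' @return scalar in [0, 1].
#' @export
diceScore <- function(c) {
  den <- 2 * c@tp + c@fp + c@fn
  if (den <= 0)
    undefinedMetricError("Dice undefined: both masks are empty")
  2 * c@tp / den
}

#' Intersection over union (Jaccard)
#'
#' `TP / (TP + FP + FN)`; undefined when both masks are empty. Related to
#' Dice by `dice = 2 * iou / (1 + iou)`, hence Dice >= IoU always.
#' @inheritParams accuracyScore
#' @return scalar in [0, 1].
#' @export
iouScore <- function(c) {
  den <- c@tp + c@fp + c@fn
  if (den <= 0)
    undefinedMetricError("IoU undefined: both masks are empty")
  c@tp / den
}
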