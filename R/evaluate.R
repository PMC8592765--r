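# Test-set evaluation and result reporting.

evalCore <- function(probs, samples, threshold, modelName) {
  rows <- list()
  skipped <- 0L
  for (k in seq_along(samples)) {
    y <- sampleMask(samples[[k]])
    pred <- binarize(probs[[k]], threshold)
    if (sum(y) == 0 && sum(pred) == 0) {
      skipped <- skipped + 1L
      next
    }
    cc <- confusionCounts(pred, y)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sampleId(samples[[k]]),
      dice = diceScore(cc), iou = iouScore(cc), accuracy = accuracyScore(cc),
      tp = cc@tp, fp = cc@fp, fn = cc@fn, tn = cc@tn)
  }
  if (skipped > 0L)
    warning(sprintf(
      "%d image(s) with empty reference and prediction skipped", skipped))
  if (!length(rows))
    undefinedMetricError("no image yielded defined metrics")
  per <- do.call(rbind, rows)
  pooled <- new("ConfusionCounts", tp = sum(per$tp), fp = sum(per$fp),
                fn = sum(per$fn), tn = sum(per$tn))
  summ <- c(dice = mean(per$dice), iou = mean(per$iou),
            accuracy = mean(per$accuracy),
            dice_pooled = diceScore(pooled), iou_pooled = iouScore(pooled),
            accuracy_pooled = accuracyScore(pooled))
  new("EvaluationResult", perImage = per, summary = summ,
      modelName = modelName)
}

#' @describeIn evaluateModel evaluate a built model: each image passes
#'   through gray-world normalisation, mean subtraction and the network;
#'   probabilities are thresholded and scored per image, and the summary is
#'   the unweighted mean over images (pooled-count variants are reported
#'   alongside).
#' @param modelName label used in reports.
setMethod("evaluateModel", "SegmentationModel",
  function(object, samples, threshold = 0.5, modelName = NULL, ...) {
    if (length(samples) == 0L) inputError("test set must be non-empty")
    probs <- lapply(samples, function(s) {
      x <- networkInput(grayWorldNormalize(sampleImage(s)))
      predictModel(object, list(x))[[1]]
    })
    if (is.null(modelName))
      modelName <- sprintf("%s/%s", object@spec@architecture,
                           object@spec@encoder)
    evalCore(probs, samples, threshold, modelName)
  })

#' @describeIn evaluateModel evaluate the best-epoch checkpoint of a
#'   training run.
setMethod("evaluateModel", "TrainingResult",
  function(object, samples, threshold = 0.5, modelName = NULL, ...) {
    m <- buildModel(object@spec)
    setWeights(m, object@checkpoint)
    evaluateModel(m, samples, threshold = threshold, modelName = modelName,
                  ...)
  })

#' @describeIn evaluateModel evaluate a plain predictor: `object` is called
#'   with the list of raw images and must return a list of probability
#'   matrices (useful for oracles and baselines).
setMethod("evaluateModel", "function",
  function(object, samples, threshold = 0.5, modelName = "predictor", ...) {
    if (length(samples) == 0L) inputError("test set must be non-empty")
    probs <- object(lapply(samples, sampleImage))
    evalCore(probs, samples, threshold, modelName)
  })

#' Tabulate evaluation summaries for model comparison
#'
#' Builds the comparison table (one row per model; columns Dice, Accuracy,
#' IoU in that order) and marks the best value per column with `*`; ties
#' are all marked.
#'
#' @param results an [EvaluationResult-class] or a list of them.
#' @param file optional path; when given the formatted table is written
#'   there as tab-separated text.
#' @return data.frame with columns `Model`, `Dice`, `Accuracy`, `IoU`
#'   (numeric) and attribute `"best"` (logical matrix of per-column
#'   maxima), invisibly. The formatted table is printed.
#' @export
reportResults <- function(results, file = NULL) {
  if (is(results, "EvaluationResult")) results <- list(results)
  df <- data.frame(
    Model = vapply(results, function(r) r@modelName, character(1)),
    Dice = vapply(results, function(r) unname(r@summary["dice"]), numeric(1)),
    Accuracy = vapply(results, function(r) unname(r@summary["accuracy"]),
                      numeric(1)),
    IoU = vapply(results, function(r) unname(r@summary["iou"]), numeric(1)))
  best <- sapply(df[c("Dice", "Accuracy", "IoU")],
                 function(v) v == max(v))
  best <- matrix(best, nrow = nrow(df),
                 dimnames = list(NULL, c("Dice", "Accuracy", "IoU")))
  fmt <- df
  for (cn in c("Dice", "Accuracy", "IoU"))
    fmt[[cn]] <- paste0(sprintf("%.4f", df[[cn]]),
                        ifelse(best[, cn], "*", ""))
  txt <- utils::capture.output(print(fmt, row.names = FALSE))
  cat(txt, sep = "\n")
  if (!is.null(file))
    utils::write.table(fmt, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  attr(df, "best") <- best
  invisible(df)
}
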