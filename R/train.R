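# Adam training loop with per-epoch validation tracing and retrospective
# best-epoch checkpointing.

#' Train a segmentation model
#'
#' Runs minibatch Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) on the
#' combined `(1 - alpha) * BCE + alpha * Dice` loss. Each epoch the
#' validation loss and metrics (Dice, IoU, accuracy at the configured
#' threshold) are recorded; the returned checkpoint holds the weights of
#' the epoch optimising `checkpointMetric` (minimum validation loss or
#' maximum validation Dice), emulating early stopping by retrospective
#' best-epoch selection. The model's weights are (re)initialised from
#' `config@seed`, which also drives shuffling, dropout and augmentation, so
#' a run is fully deterministic on one device.
#'
#' Input pipeline: gray-world colour constancy, then (training only)
#' stochastic augmentation, then ImageNet channel-mean subtraction and
#' scaling to unit range. When the augmentation policy defines a crop with
#' `applyToValidation`, validation images are cropped with a fixed
#' per-epoch seed so curves stay comparable.
#'
#' @param model a [SegmentationModel-class] (weights are re-initialised).
#' @param trainSamples,valSamples non-empty lists of
#'   [DermoscopySample-class]; all samples of a set must share one
#'   stride-compatible size (see [resizePair()]).
#' @param config a [TrainingConfig-class].
#' @param augment optional [AugmentPolicy-class]; `NULL` disables
#'   augmentation.
#' @param verbose print one line per epoch.
#' @return A [TrainingResult-class].
#' @export
trainModel <- function(model, trainSamples, valSamples, config,
                       augment = NULL, verbose = FALSE) {
  validObject(config)
  if (length(trainSamples) == 0L || length(valSamples) == 0L)
    inputError("train and validation sets must be non-empty")
  seed <- config@seed
  alpha <- config@alpha

  gwSample <- function(s)
    dermoscopySample(sampleId(s), grayWorldNormalize(sampleImage(s)),
                     sampleMask(s), sampleSource(s))
  trainGw <- lapply(trainSamples, gwSample)
  valGw <- lapply(valSamples, gwSample)

  valPol <- if (!is.null(augment)) validationPolicy(augment) else NULL
  cropActive <- !is.null(valPol) && !anyNA(valPol@cropSize)

  eng_init(model@ptr, seed)
  nTrain <- length(trainGw)
  bs <- config@batchSize
  # batches for per-epoch BN re-estimation ("precise BN"): with small
  # minibatches the exponential running statistics lag the weights, so
  # evaluation-mode forwards drift from training-mode behaviour; exact
  # statistics over a fixed training subset remove that drift
  bnBatches <- local({
    idx <- seq_len(min(64L, nTrain))
    split(idx, ceiling(seq_along(idx) / 8L))
  })
  bnInputs <- lapply(bnBatches, function(ii)
    imagesToBatch(lapply(trainGw[ii],
                         function(s) networkInput(sampleImage(s)))))
  hist <- vector("list", config@epochs)
  bestVal <- Inf
  bestW <- NULL
  bestEpoch <- NA_integer_

  for (epoch in seq_len(config@epochs)) {
    set.seed(substreamSeed(seed, epoch))
    order <- sample.int(nTrain)
    losses <- numeric(0)
    b0 <- 1L
    batchIdx <- 0L
    while (b0 <= nTrain) {
      idx <- order[b0:min(nTrain, b0 + bs - 1L)]
      batchIdx <- batchIdx + 1L
      ss <- trainGw[idx]
      if (!is.null(augment))
        ss <- lapply(ss, augmentSample, policy = augment)
      xs <- lapply(ss, function(s) networkInput(sampleImage(s)))
      ys <- lapply(ss, sampleMask)
      b <- imagesToBatch(xs)
      checkStrideBudget(b$dims[3:4])
      res <- eng_train_step(model@ptr, b$x, as.integer(b$dims),
                            masksToBatch(ys), alpha, config@learningRate,
                            0.9, 0.999, 1e-8)
      if (!is.finite(res$loss))
        divergenceError(sprintf(
          "non-finite training loss at epoch %d, batch %d", epoch, batchIdx))
      losses <- c(losses, res$loss)
      b0 <- b0 + bs
    }

    # re-estimate batch-norm running statistics before evaluating
    eng_bn_begin_accum(model@ptr)
    for (bb in bnInputs)
      eng_forward(model@ptr, bb$x, as.integer(bb$dims), TRUE)
    eng_bn_finish_accum(model@ptr)

    # validation pass (eval mode, deterministic; fixed per-epoch crop seed)
    set.seed(substreamSeed(seed, 100000L + epoch))
    vs <- valGw
    if (cropActive) vs <- lapply(vs, augmentSample, policy = valPol)
    vm <- evalOnSamples(model, vs, config@threshold, alpha,
                        preGrayWorld = TRUE)
    rec <- data.frame(epoch = epoch, train_loss = mean(losses),
                      val_loss = vm$loss, val_dice = vm$dice,
                      val_iou = vm$iou, val_accuracy = vm$accuracy)
    hist[[epoch]] <- rec
    score <- if (config@checkpointMetric == "val_loss") vm$loss else -vm$dice
    if (score < bestVal) {
      bestVal <- score
      bestW <- eng_get_params(model@ptr)
      bestEpoch <- epoch
    }
    if (verbose)
      message(sprintf(
        "epoch %3d  train %.4f  val %.4f  dice %.4f  iou %.4f  acc %.4f",
        epoch, rec$train_loss, rec$val_loss, rec$val_dice, rec$val_iou,
        rec$val_accuracy))
  }
  new("TrainingResult", history = do.call(rbind, hist),
      bestEpoch = bestEpoch, checkpoint = bestW,
      finalWeights = eng_get_params(model@ptr), spec = model@spec,
      config = config)
}

# Forward a list of (gray-world-normalised if preGrayWorld) samples in eval
# mode and compute mean per-image loss and metrics.
evalOnSamples <- function(model, samples, threshold, alpha,
                          preGrayWorld = FALSE, batch = 8L) {
  n <- length(samples)
  loss <- dice <- iou <- acc <- numeric(0)
  skipped <- 0L
  b0 <- 1L
  while (b0 <= n) {
    idx <- b0:min(n, b0 + batch - 1L)
    xs <- lapply(samples[idx], function(s) {
      img <- sampleImage(s)
      if (!preGrayWorld) img <- grayWorldNormalize(img)
      networkInput(img)
    })
    zs <- modelForward(model, xs, train = FALSE)
    for (k in seq_along(idx)) {
      y <- sampleMask(samples[[idx[k]]])
      p <- 1 / (1 + exp(-zs[[k]]))
      loss <- c(loss, combinedLoss(p, y, alpha))
      pred <- binarize(p, threshold)
      if (sum(y) == 0 && sum(pred) == 0) {
        skipped <- skipped + 1L
        next
      }
      cc <- confusionCounts(pred, y)
      dice <- c(dice, diceScore(cc))
      iou <- c(iou, iouScore(cc))
      acc <- c(acc, accuracyScore(cc))
    }
    b0 <- b0 + batch
  }
  if (skipped > 0L)
    warning(sprintf(
      "%d image(s) with empty reference and prediction skipped in metrics",
      skipped))
  list(loss = mean(loss), dice = mean(dice), iou = mean(iou),
       accuracy = mean(acc))
}

#' Write a training history as delimited text
#'
#' One row per epoch with `epoch`, `train_loss`, `val_loss`, `val_dice`,
#' `val_iou`, `val_accuracy` -- the data behind loss/Dice training curves.
#'
#' @param history data.frame from a [TrainingResult-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeHistory <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
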