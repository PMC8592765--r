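#' @import methods
NULL

# ---------------------------------------------------------------------------
# Central S4 classes. All raster data use the package-wide convention:
# images are H x W x 3 double arrays on the 0..255 scale at ingest, masks are
# H x W matrices with values in {0, 1}.
# ---------------------------------------------------------------------------

#' DermoscopySample: one dermoscopic image with its binary lesion mask
#'
#' The elementary unit of data in dermaseg: an RGB dermoscopic image
#' (H x W x 3 array, intensities on the 0--255 scale at ingest) paired with a
#' pixel-aligned binary lesion mask (H x W matrix with values in \{0, 1\};
#' 1 marks lesion pixels), a stable sample identifier, and the provenance of
#' the pair (`"isic"`, `"ph2"` or `"synthetic"`).
#'
#' Validity requires matching image/mask dimensions, a strictly binary mask,
#' and both sides at least 32 pixels (the stride budget of the deepest
#' encoder levels).
#'
#' @slot sampleId character(1), stable identifier.
#' @slot image numeric array H x W x 3.
#' @slot mask numeric matrix H x W, values in \{0, 1\}.
#' @slot source character(1), one of `"isic"`, `"ph2"`, `"synthetic"`.
#' @seealso [dermoscopySample()], [readIsicPair()], [readPh2Case()],
#'   [generateSample()]
#' @export
setClass("DermoscopySample",
  representation(sampleId = "character", image = "array",
                 mask = "matrix", source = "character"))

setValidity("DermoscopySample", function(object) {
  msg <- character()
  di <- dim(object@image)
  dm <- dim(object@mask)
  if (length(di) != 3L || di[3] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (length(di) == 3L && !identical(di[1:2], dm))
    msg <- c(msg, sprintf("image (%s) and mask (%s) dimensions differ",
                          paste(di[1:2], collapse = "x"),
                          paste(dm, collapse = "x")))
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask values must be exactly 0 or 1")
  if (any(dm < 32L))
    msg <- c(msg, "mask/image must be at least 32 x 32")
  if (!object@source %in% c("isic", "ph2", "synthetic"))
    msg <- c(msg, "source must be one of 'isic', 'ph2', 'synthetic'")
  if (length(msg)) msg else TRUE
})

#' Construct a DermoscopySample
#'
#' @param sampleId character(1) identifier.
#' @param image H x W x 3 numeric array, 0--255 scale.
#' @param mask H x W numeric matrix with values in \{0,1\}.
#' @param source `"isic"`, `"ph2"` or `"synthetic"`.
#' @return A [DermoscopySample-class] object.
#' @examples
#' img <- array(128, c(64, 64, 3))
#' msk <- matrix(0, 64, 64); msk[20:40, 20:40] <- 1
#' s <- dermoscopySample("toy", img, msk, "synthetic")
#' @export
dermoscopySample <- function(sampleId, image, mask, source = "synthetic") {
  new("DermoscopySample", sampleId = as.character(sampleId),
      image = image, mask = as.matrix(mask), source = source)
}

#' @describeIn DermoscopySample-class compact display
#' @param object a `DermoscopySample`
#' @export
setMethod("show", "DermoscopySample", function(object) {
  d <- dim(object@mask)
  cat(sprintf("DermoscopySample '%s' [%s] %dx%d, lesion fraction %.3f\n",
              object@sampleId, object@source, d[1], d[2],
              mean(object@mask)))
})

#' DatasetSplit: disjoint train/validation/test partition of sample ids
#'
#' @slot train character vector of sample ids.
#' @slot validation character vector of sample ids.
#' @slot test character vector of sample ids.
#' @seealso [splitDataset()]
#' @export
setClass("DatasetSplit",
  representation(train = "character", validation = "character",
                 test = "character"))

setValidity("DatasetSplit", function(object) {
  ids <- c(object@train, object@validation, object@test)
  if (anyDuplicated(ids))
    "train/validation/test must be pairwise disjoint" else TRUE
})

#' @describeIn DatasetSplit-class compact display
#' @param object a `DatasetSplit`
#' @export
setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d validation / %d test\n",
              length(object@train), length(object@validation),
              length(object@test)))
})

#' AugmentPolicy: stochastic augmentation policy for image/mask pairs
#'
#' Describes the seven-operation augmentation family applied during
#' training: random scaling, random rotation, horizontal/vertical flips,
#' brightness/contrast shifts, contrast-limited adaptive histogram
#' equalisation (CLAHE), random cropping and HSV colour shifts. Geometric
#' operations are applied jointly to image and mask; photometric operations
#' touch the image only. Random cropping is the one operation also applied
#' to validation images when `applyToValidation` is `TRUE` (the default).
#'
#' @slot scaleRange numeric(2), multiplicative scale range (lo <= hi).
#' @slot rotationRange numeric(2), rotation range in degrees.
#' @slot hflipProb numeric(1), horizontal flip probability.
#' @slot vflipProb numeric(1), vertical flip probability.
#' @slot brightnessRange numeric(2), additive shift as a fraction of 255.
#' @slot contrastRange numeric(2), relative contrast change.
#' @slot claheProb numeric(1), probability of adaptive histogram equalisation.
#' @slot claheClip numeric(1), CLAHE clip limit.
#' @slot cropSize integer(2) or NA, crop height/width in pixels.
#' @slot hsvShift numeric(3), max hue (degrees), saturation and value
#'   (0--255 units) shifts.
#' @slot applyToValidation logical(1), apply the crop to validation images.
#' @seealso [augmentPolicy()], [augmentSample()]
#' @export
setClass("AugmentPolicy",
  representation(scaleRange = "numeric", rotationRange = "numeric",
                 hflipProb = "numeric", vflipProb = "numeric",
                 brightnessRange = "numeric", contrastRange = "numeric",
                 claheProb = "numeric", claheClip = "numeric",
                 cropSize = "integer", hsvShift = "numeric",
                 applyToValidation = "logical"))

setValidity("AugmentPolicy", function(object) {
  msg <- character()
  rng <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2])
      sprintf("%s must be an ordered pair (lo <= hi)", nm) else character()
  }
  msg <- c(msg, rng(object@scaleRange, "scaleRange"),
           rng(object@rotationRange, "rotationRange"),
           rng(object@brightnessRange, "brightnessRange"),
           rng(object@contrastRange, "contrastRange"))
  for (p in c(object@hflipProb, object@vflipProb, object@claheProb))
    if (p < 0 || p > 1) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an augmentation policy
#'
#' Defaults are conventional dermoscopy magnitudes: mild scaling (0.9--1.1),
#' rotations up to 30 degrees, 50% flips, 20% brightness/contrast
#' shifts, occasional CLAHE, and HSV shifts of at most 10 units. A value of
#' `0` (or a degenerate range) disables an operation; `cropSize = NA`
#' disables cropping.
#'
#' @param scaleRange numeric(2) multiplicative scale range.
#' @param rotationRange numeric(2) rotation range, degrees.
#' @param hflipProb,vflipProb flip probabilities.
#' @param brightnessRange numeric(2) additive shift, fraction of 255.
#' @param contrastRange numeric(2) relative contrast change.
#' @param claheProb probability of CLAHE.
#' @param claheClip CLAHE clip limit.
#' @param cropSize integer(1 or 2) crop size in pixels, or NA.
#' @param hsvShift numeric(3) max hue (deg), saturation, value (0--255) shifts.
#' @param applyToValidation logical, apply the crop on validation images too.
#' @return An [AugmentPolicy-class] object.
#' @export
augmentPolicy <- function(scaleRange = c(0.9, 1.1),
                          rotationRange = c(-30, 30),
                          hflipProb = 0.5, vflipProb = 0.5,
                          brightnessRange = c(-0.2, 0.2),
                          contrastRange = c(-0.2, 0.2),
                          claheProb = 0.25, claheClip = 2,
                          cropSize = NA, hsvShift = c(10, 10, 10),
                          applyToValidation = TRUE) {
  if (length(cropSize) == 1L) cropSize <- rep(cropSize, 2L)
  new("AugmentPolicy", scaleRange = as.numeric(scaleRange),
      rotationRange = as.numeric(rotationRange),
      hflipProb = hflipProb, vflipProb = vflipProb,
      brightnessRange = as.numeric(brightnessRange),
      contrastRange = as.numeric(contrastRange),
      claheProb = claheProb, claheClip = claheClip,
      cropSize = as.integer(cropSize), hsvShift = as.numeric(hsvShift),
      applyToValidation = applyToValidation)
}

#' A policy with every stochastic operation disabled
#'
#' Useful as a baseline and for validation pipelines without cropping.
#' @return An [AugmentPolicy-class] with all operations off.
#' @export
noAugmentPolicy <- function() {
  augmentPolicy(scaleRange = c(1, 1), rotationRange = c(0, 0),
                hflipProb = 0, vflipProb = 0,
                brightnessRange = c(0, 0), contrastRange = c(0, 0),
                claheProb = 0, cropSize = NA, hsvShift = c(0, 0, 0),
                applyToValidation = FALSE)
}

#' ModelSpec: declarative description of a segmentation architecture
#'
#' @slot architecture `"unet"`, `"unetpp_dense"` or `"unetpp_improved"`.
#' @slot encoder `"plain"`, `"efficientnet_b0"` or `"xception"`.
#' @slot encoderPretrained logical; when `TRUE`, [buildModel()] expects a
#'   weights file to load (no download is ever performed).
#' @slot decoderWidths integer(5), decoder node channels at encoder depths
#'   1..5 (shallow to deep; the fifth entry is reserved: the deepest level
#'   carries no decoder node).
#' @slot baseWidth integer(1), first-level channels of the plain encoder.
#' @slot activation `"relu"`, `"prelu"`, `"gelu"`, `"swish"` or `"mish"`.
#' @slot dropoutRate numeric(1) in [0, 1), spatial dropout after decoder nodes.
#' @slot batchNorm logical(1), batch normalisation in decoder/plain-encoder
#'   convolution blocks.
#' @slot deepSupervision logical(1), attach a loss head to every decoder
#'   column (nested decoders only).
#' @slot inChannels,outChannels integer(1).
#' @seealso [modelSpec()], [buildModel()]
#' @export
setClass("ModelSpec",
  representation(architecture = "character", encoder = "character",
                 encoderPretrained = "logical", decoderWidths = "integer",
                 baseWidth = "integer", activation = "character",
                 dropoutRate = "numeric", batchNorm = "logical",
                 deepSupervision = "logical", inChannels = "integer",
                 outChannels = "integer"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@architecture %in% c("unet", "unetpp_dense", "unetpp_improved"))
    msg <- c(msg, "unknown architecture")
  if (!object@encoder %in% c("plain", "efficientnet_b0", "xception"))
    msg <- c(msg, "unknown encoder")
  if (!object@activation %in% c("relu", "prelu", "gelu", "swish", "mish"))
    msg <- c(msg, "unknown activation")
  if (length(object@decoderWidths) != 5L || any(object@decoderWidths <= 0L))
    msg <- c(msg, "decoderWidths must be 5 strictly positive integers")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (object@baseWidth < 1L) msg <- c(msg, "baseWidth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelSpec-class compact display
#' @param object a `ModelSpec`
#' @export
setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s / %s encoder / %s, widths (%s), dropout %.2f%s%s\n",
              object@architecture, object@encoder, object@activation,
              paste(object@decoderWidths, collapse = ","),
              object@dropoutRate,
              if (object@batchNorm) ", BN" else "",
              if (object@deepSupervision) ", deep supervision" else ""))
})

#' TrainingConfig: optimiser, loss and checkpoint settings
#'
#' @slot learningRate numeric(1) > 0 (Adam step size; default 1e-4).
#' @slot batchSize integer(1) >= 1 (default 2).
#' @slot epochs integer(1) >= 1.
#' @slot alpha numeric(1) in [0, 1], weight of the Dice term in the combined
#'   loss; `1 - alpha` weights the binary cross-entropy term.
#' @slot seed integer(1), governs initialisation, shuffling, dropout and
#'   augmentation.
#' @slot checkpointMetric `"val_loss"` (minimised) or `"val_dice"`
#'   (maximised); selects the retrospective best epoch.
#' @slot threshold numeric(1), probability binarisation threshold.
#' @slot device character(1); only `"cpu"` is available.
#' @seealso [trainingConfig()], [trainModel()]
#' @export
setClass("TrainingConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", alpha = "numeric", seed = "integer",
                 checkpointMetric = "character", threshold = "numeric",
                 device = "character"))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (!object@checkpointMetric %in% c("val_loss", "val_dice"))
    msg <- c(msg, "checkpointMetric must be 'val_loss' or 'val_dice'")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainingConfig
#'
#' @param learningRate Adam step size (default 1e-4).
#' @param batchSize minibatch size (default 2).
#' @param epochs number of epochs.
#' @param alpha Dice weight of the combined loss, in [0, 1].
#' @param seed integer seed for the whole run.
#' @param checkpointMetric `"val_loss"` or `"val_dice"`.
#' @param threshold probability binarisation threshold.
#' @param device `"cpu"`.
#' @return A [TrainingConfig-class] object.
#' @export
trainingConfig <- function(learningRate = 1e-4, batchSize = 2L, epochs = 100L,
                           alpha = 0.5, seed = 1L,
                           checkpointMetric = "val_loss", threshold = 0.5,
                           device = "cpu") {
  new("TrainingConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      alpha = alpha, seed = as.integer(seed),
      checkpointMetric = checkpointMetric, threshold = threshold,
      device = device)
}

#' SyntheticConfig: parameters of the synthetic dermoscopy generator
#'
#' @slot nSamples integer(1), number of image/mask pairs.
#' @slot size integer(2), (H, W), multiples of 32.
#' @slot lesionAreaRange numeric(2), lesion area as a fraction of image area.
#' @slot boundaryIrregularity numeric(1) >= 0, radial harmonic amplitude.
#' @slot lesionContrast numeric(1) in (0, 1], relative darkening of the
#'   lesion interior.
#' @slot hairProbability numeric(1) in [0, 1].
#' @slot illuminationGradient numeric(1) >= 0, relative strength of the
#'   linear illumination ramp.
#' @slot noiseSd numeric(1) >= 0, Gaussian pixel noise sd (0--255 scale).
#' @slot seed integer(1); per-sample substreams are derived by counter.
#' @seealso [syntheticConfig()], [generateSample()], [generateDataset()]
#' @export
setClass("SyntheticConfig",
  representation(nSamples = "integer", size = "integer",
                 lesionAreaRange = "numeric", boundaryIrregularity = "numeric",
                 lesionContrast = "numeric", hairProbability = "numeric",
                 illuminationGradient = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  r <- object@lesionAreaRange
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2])
    msg <- c(msg, "lesionAreaRange must satisfy 0 < lo < hi < 1")
  if (object@hairProbability < 0 || object@hairProbability > 1)
    msg <- c(msg, "hairProbability must lie in [0, 1]")
  if (object@lesionContrast <= 0 || object@lesionContrast > 1)
    msg <- c(msg, "lesionContrast must lie in (0, 1]")
  if (object@boundaryIrregularity < 0)
    msg <- c(msg, "boundaryIrregularity must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(object@size < 32L) || any(object@size %% 32L != 0L))
    msg <- c(msg, "size must be multiples of 32, each >= 32")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticConfig
#'
#' Defaults emulate a 64 x 64 dermoscopy crop: a darker, irregular,
#' star-convex lesion blob (5--35% of image area) on a textured skin
#' background with a mild illumination ramp, pixel noise, and occasional
#' hair arcs drawn over the image only.
#'
#' @param nSamples number of samples.
#' @param size (H, W), multiples of 32.
#' @param lesionAreaRange lesion area fraction range, 0 < lo < hi < 1.
#' @param boundaryIrregularity radial perturbation amplitude (0 = ellipse).
#' @param lesionContrast relative darkening of the lesion, in (0, 1].
#' @param hairProbability probability a sample receives hair artifacts.
#' @param illuminationGradient relative strength of the illumination ramp.
#' @param noiseSd Gaussian noise sd on the 0--255 scale.
#' @param seed integer master seed.
#' @return A [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(nSamples = 200L, size = c(64L, 64L),
                            lesionAreaRange = c(0.05, 0.35),
                            boundaryIrregularity = 0.15,
                            lesionContrast = 0.45, hairProbability = 0.3,
                            illuminationGradient = 0.15, noiseSd = 6,
                            seed = 1L) {
  if (length(size) == 1L) size <- rep(size, 2L)
  new("SyntheticConfig", nSamples = as.integer(nSamples),
      size = as.integer(size), lesionAreaRange = as.numeric(lesionAreaRange),
      boundaryIrregularity = boundaryIrregularity,
      lesionContrast = lesionContrast, hairProbability = hairProbability,
      illuminationGradient = illuminationGradient, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' ConfusionCounts: pixel-level confusion-matrix tallies
#'
#' True/false positive/negative pixel counts from which all segmentation
#' metrics derive: accuracy = (TP+TN)/(TP+TN+FP+FN),
#' Dice = 2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN).
#'
#' @slot tp,fp,fn,tn numeric(1) non-negative pixel counts.
#' @seealso [confusionCounts()], [diceScore()], [iouScore()],
#'   [accuracyScore()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0) || any(v != round(v)))
    "counts must be non-negative integers" else TRUE
})

#' @describeIn ConfusionCounts-class compact display
#' @param object a `ConfusionCounts`
#' @export
setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              as.integer(object@tp), as.integer(object@fp),
              as.integer(object@fn), as.integer(object@tn),
              as.integer(object@tp + object@fp + object@fn + object@tn)))
})

#' SegmentationModel: a built network bound to its specification
#'
#' Wraps the native compute graph together with the [ModelSpec-class] that
#' produced it and the bookkeeping needed to read encoder taps. The native
#' handle is session-bound; persist models as checkpoints
#' ([saveCheckpoint()]) holding the spec plus the flat weight vector.
#'
#' @slot ptr external pointer to the native graph.
#' @slot spec the [ModelSpec-class].
#' @slot tapNodes integer(5), graph nodes of the encoder pyramid.
#' @slot tapChannels integer(5), channels at each tap.
#' @slot tapStrides integer(5), stride of each tap relative to the input.
#' @slot outputNodes integer, loss-head node(s).
#' @seealso [buildModel()], [countTrainableParameters()],
#'   [encoderFeatures()], [predictModel()]
#' @export
setClass("SegmentationModel",
  representation(ptr = "externalptr", spec = "ModelSpec",
                 tapNodes = "integer", tapChannels = "integer",
                 tapStrides = "integer", outputNodes = "integer"))

#' @describeIn SegmentationModel-class compact display
#' @param object a `SegmentationModel`
#' @export
setMethod("show", "SegmentationModel", function(object) {
  cat(sprintf("SegmentationModel (%s / %s): %s trainable parameters\n",
              object@spec@architecture, object@spec@encoder,
              format(countTrainableParameters(object), big.mark = ",")))
})

#' TrainingResult: history, best epoch and checkpoint of one training run
#'
#' @slot history data.frame with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `val_dice`, `val_iou`, `val_accuracy`.
#' @slot bestEpoch integer(1), epoch optimising the checkpoint metric.
#' @slot checkpoint numeric vector, flat weights at the best epoch.
#' @slot finalWeights numeric vector, weights after the last epoch.
#' @slot spec the [ModelSpec-class] that was trained.
#' @slot config the [TrainingConfig-class] used.
#' @seealso [trainModel()], [evaluateModel()]
#' @export
setClass("TrainingResult",
  representation(history = "data.frame", bestEpoch = "integer",
                 checkpoint = "numeric", finalWeights = "numeric",
                 spec = "ModelSpec", config = "TrainingConfig"))

#' @describeIn TrainingResult-class compact display
#' @param object a `TrainingResult`
#' @export
setMethod("show", "TrainingResult", function(object) {
  h <- object@history
  cat(sprintf("TrainingResult: %d epochs, best epoch %d (val_loss %.4f, val_dice %.4f)\n",
              nrow(h), object@bestEpoch,
              h$val_loss[object@bestEpoch], h$val_dice[object@bestEpoch]))
})

#' EvaluationResult: per-image metrics and dataset summary
#'
#' @slot perImage data.frame: `sample_id`, `dice`, `iou`, `accuracy`,
#'   `tp`, `fp`, `fn`, `tn`.
#' @slot summary named numeric: unweighted means `dice`, `iou`, `accuracy`
#'   (and pooled-count variants `dice_pooled`, `iou_pooled`,
#'   `accuracy_pooled`).
#' @slot modelName character(1).
#' @seealso [evaluateModel()], [reportResults()]
#' @export
setClass("EvaluationResult",
  representation(perImage = "data.frame", summary = "numeric",
                 modelName = "character"))

#' @describeIn EvaluationResult-class compact display
#' @param object an `EvaluationResult`
#' @export
setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult '%s' over %d images: Dice %.4f, IoU %.4f, accuracy %.4f\n",
              object@modelName, nrow(object@perImage),
              object@summary["dice"], object@summary["iou"],
              object@summary["accuracy"]))
})
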