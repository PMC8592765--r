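# Model construction and inference.

#' Construct a ModelSpec
#'
#' The default configuration is the package's reference model: the pruned
#' nested decoder (`unetpp_improved`) over an EfficientNet-B0 encoder with
#' decoder widths 16/32/64/128 shallow-to-deep, batch normalisation, ReLU,
#' spatial dropout 0.2 and a single head.
#'
#' @param architecture `"unet"`, `"unetpp_dense"` or `"unetpp_improved"`.
#' @param encoder `"plain"`, `"efficientnet_b0"` or `"xception"`.
#' @param encoderPretrained logical; `TRUE` requires `encoderWeights` at
#'   [buildModel()] time (weights are never downloaded).
#' @param decoderWidths integer(5), decoder node channels shallow to deep
#'   (the fifth entry is reserved; the deepest level has no decoder node).
#' @param baseWidth plain-encoder first-level channels (doubling rule gives
#'   e.g. 8,16,32,64,128).
#' @param activation decoder/plain-encoder activation: `"relu"`, `"prelu"`,
#'   `"gelu"`, `"swish"` or `"mish"`. Backbone encoders keep their canonical
#'   internal activations.
#' @param dropoutRate spatial dropout after each decoder node, in [0, 1).
#' @param batchNorm batch-normalise decoder/plain-encoder conv blocks.
#' @param deepSupervision attach a head to every nested-decoder column.
#' @param inChannels,outChannels input/output channel counts.
#' @return A [ModelSpec-class].
#' @examples
#' modelSpec("unet", "plain", baseWidth = 8)
#' modelSpec()  # the reference configuration
#' @export
modelSpec <- function(architecture = "unetpp_improved",
                      encoder = "efficientnet_b0",
                      encoderPretrained = FALSE,
                      decoderWidths = c(16L, 32L, 64L, 128L, 256L),
                      baseWidth = 8L, activation = "relu",
                      dropoutRate = 0.2, batchNorm = TRUE,
                      deepSupervision = FALSE, inChannels = 3L,
                      outChannels = 1L) {
  new("ModelSpec", architecture = architecture, encoder = encoder,
      encoderPretrained = encoderPretrained,
      decoderWidths = as.integer(decoderWidths),
      baseWidth = as.integer(baseWidth), activation = activation,
      dropoutRate = dropoutRate, batchNorm = batchNorm,
      deepSupervision = deepSupervision,
      inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels))
}

#' Build a segmentation model from its specification
#'
#' Instantiates the native compute graph (encoder, decoder, heads) and
#' initialises weights: fan-out-scaled He-normal for convolutions,
#' ones/zeros for batch norm, 0.25 for PReLU slopes. The model maps `inChannels x H x W` batches
#' (H, W multiples of 32) to `outChannels x H x W` logits; the sigmoid is
#' applied at prediction time, never inside the forward map.
#'
#' @param spec a [ModelSpec-class].
#' @param initSeed integer seed for weight initialisation.
#' @param encoderWeights optional path to a checkpoint written by
#'   [saveCheckpoint()] whose weights are loaded after initialisation
#'   (required when `spec@encoderPretrained` is `TRUE`).
#' @return A [SegmentationModel-class].
#' @examples
#' m <- buildModel(modelSpec("unet", "plain", baseWidth = 4), initSeed = 1)
#' countTrainableParameters(m)
#' @export
buildModel <- function(spec, initSeed = 42L, encoderWeights = NULL) {
  validObject(spec)
  g <- newGraph()
  g$channels[1] <- spec@inChannels
  enc <- buildEncoder(g, 1L, spec)
  heads <- buildDecoder(g, enc, spec)
  ptr <- buildEngine(g, heads)
  eng_init(ptr, as.integer(initSeed))
  model <- new("SegmentationModel", ptr = ptr, spec = spec,
               tapNodes = as.integer(enc$taps),
               tapChannels = as.integer(enc$channels),
               tapStrides = as.integer(enc$strides),
               outputNodes = as.integer(heads))
  if (spec@encoderPretrained && is.null(encoderWeights))
    configError(
      "encoderPretrained = TRUE requires an encoderWeights checkpoint file")
  if (!is.null(encoderWeights)) {
    ck <- loadCheckpoint(encoderWeights)
    setWeights(model, ck$weights)
  }
  model
}

# --- batch conversion (R arrays <-> flat NCHW) ---

imagesToBatch <- function(images) {
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1]])
  flat <- unlist(lapply(images, function(im) {
    if (!identical(dim(im), d)) validationError("batch images differ in shape")
    as.vector(aperm(im, c(2L, 1L, 3L)))
  }), use.names = FALSE)
  list(x = flat, dims = c(length(images), d[3], d[1], d[2]))
}

masksToBatch <- function(masks) {
  if (!is.list(masks)) masks <- list(masks)
  unlist(lapply(masks, function(m) as.vector(t(m))), use.names = FALSE)
}

batchToList <- function(res) {
  td <- attr(res, "tdim")
  arr <- array(res, dim = c(td[4], td[3], td[2], td[1]))
  lapply(seq_len(td[1]), function(ni) t(arr[, , 1, ni]))
}

checkStrideBudget <- function(d) {
  if (any(d[1:2] %% 32L != 0L) || any(d[1:2] < 32L))
    validationError(sprintf(
      "input %s is not a multiple of 32; resize first (encoder stride budget)",
      paste(d[1:2], collapse = "x")))
}

#' Forward pass returning logits
#'
#' @param model a [SegmentationModel-class].
#' @param images one `H x W x C` array or a list of them (already
#'   network-normalised); H and W must be multiples of 32.
#' @param train logical; training mode enables batch-statistics
#'   normalisation and dropout.
#' @return list of `H x W` logit matrices, one per image.
#' @export
modelForward <- function(model, images, train = FALSE) {
  b <- imagesToBatch(images)
  checkStrideBudget(b$dims[3:4])
  res <- eng_forward(model@ptr, b$x, as.integer(b$dims), train)
  batchToList(res)
}

#' Predict lesion probabilities
#'
#' Forward pass followed by the sigmoid; use [binarize()] to obtain masks.
#'
#' @inheritParams modelForward
#' @return list of `H x W` probability matrices.
#' @export
predictModel <- function(model, images) {
  lapply(modelForward(model, images, train = FALSE),
         function(z) 1 / (1 + exp(-z)))
}

#' Extract the encoder feature pyramid
#'
#' Runs the encoder on a batch and returns the five pyramid levels. For the
#' backbone encoders the levels sit at strides 2, 4, 8, 16, 32 with
#' channels (16, 24, 40, 112, 320) for EfficientNet-B0 and (64, 128, 256,
#' 728, 2048) for Xception; the plain encoder uses strides 1..16 with
#' doubling channels from `baseWidth`.
#'
#' @inheritParams modelForward
#' @return list with `maps` (list of `N x C x h x w` arrays), `channels`
#'   and `strides`.
#' @export
encoderFeatures <- function(model, images) {
  b <- imagesToBatch(images)
  checkStrideBudget(b$dims[3:4])
  outs <- eng_node_outputs(model@ptr, b$x, as.integer(b$dims),
                           as.integer(model@tapNodes - 1L))
  maps <- lapply(outs, function(res) {
    td <- attr(res, "tdim")
    aperm(array(res, dim = c(td[4], td[3], td[2], td[1])), c(4L, 3L, 2L, 1L))
  })
  list(maps = maps, channels = model@tapChannels,
       strides = model@tapStrides)
}

#' Count trainable parameters
#'
#' Sums element counts over all trainable tensors: convolution weights and
#' biases, batch-norm scale/shift pairs and PReLU slopes. Batch-norm
#' running statistics are excluded. The count is an architecture property,
#' invariant to the input size.
#'
#' @param model a [SegmentationModel-class].
#' @return integer-valued numeric(1).
#' @export
countTrainableParameters <- function(model) {
  eng_nparams(model@ptr)
}

#' Get / set the flat weight vector
#'
#' The flat vector holds all trainable parameters plus batch-norm running
#' statistics, in graph order; it is the package's checkpoint payload.
#'
#' @param model a [SegmentationModel-class].
#' @return `getWeights`: numeric vector.
#' @export
getWeights <- function(model) eng_get_params(model@ptr)

#' @rdname getWeights
#' @param weights numeric vector as returned by `getWeights`.
#' @export
setWeights <- function(model, weights) {
  eng_set_params(model@ptr, as.numeric(weights))
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the [ModelSpec-class] and the flat weight vector;
#' [loadCheckpoint()] plus [buildModel()] reconstruct the model exactly.
#'
#' @param object a [SegmentationModel-class] or [TrainingResult-class]
#'   (its best-epoch weights are saved).
#' @param path file path.
#' @return `saveCheckpoint`: the path, invisibly; `loadCheckpoint`: a list
#'   with `spec` and `weights`; `restoreModel`: a [SegmentationModel-class].
#' @export
saveCheckpoint <- function(object, path) {
  payload <-
    if (is(object, "TrainingResult"))
      list(spec = object@spec, weights = object@checkpoint,
           bestEpoch = object@bestEpoch)
    else list(spec = object@spec, weights = getWeights(object),
              bestEpoch = NA_integer_)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) inputError(sprintf("no such checkpoint: '%s'", path))
  readRDS(path)
}

#' @rdname saveCheckpoint
#' @param checkpoint a list as returned by `loadCheckpoint`.
#' @export
restoreModel <- function(checkpoint) {
  m <- buildModel(checkpoint$spec)
  setWeights(m, checkpoint$weights)
  m
}
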