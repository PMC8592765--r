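#' @include AllClasses.R
NULL

#' Accessors for DermoscopySample
#'
#' @param x a [DermoscopySample-class]
#' @return `sampleId`: character(1); `sampleImage`: H x W x 3 array;
#'   `sampleMask`: H x W \{0,1\} matrix; `sampleSource`: character(1).
#' @name sample-accessors
NULL

#' @rdname sample-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname sample-accessors
#' @export
setGeneric("sampleImage", function(x) standardGeneric("sampleImage"))

#' @rdname sample-accessors
#' @export
setGeneric("sampleMask", function(x) standardGeneric("sampleMask"))

#' @rdname sample-accessors
#' @export
setGeneric("sampleSource", function(x) standardGeneric("sampleSource"))

#' @rdname sample-accessors
setMethod("sampleId", "DermoscopySample", function(x) x@sampleId)

#' @rdname sample-accessors
setMethod("sampleImage", "DermoscopySample", function(x) x@image)

#' @rdname sample-accessors
setMethod("sampleMask", "DermoscopySample", function(x) x@mask)

#' @rdname sample-accessors
setMethod("sampleSource", "DermoscopySample", function(x) x@source)

#' Confusion-count accessor
#'
#' @param x a [ConfusionCounts-class]
#' @return named numeric vector `c(tp, fp, fn, tn)`.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname counts
setMethod("counts", "ConfusionCounts", function(x)
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))

#' Evaluate a segmentation model (or predictor) on a test set
#'
#' @param object what to evaluate: a [SegmentationModel-class], a
#'   [TrainingResult-class] (its best-epoch checkpoint is used), or a
#'   plain predictor `function(imageBatch)` returning probabilities.
#' @param samples list of [DermoscopySample-class] test samples.
#' @param threshold probability binarisation threshold (default 0.5).
#' @param ... further arguments passed to methods.
#' @return An [EvaluationResult-class].
#' @export
setGeneric("evaluateModel",
           function(object, samples, threshold = 0.5, ...)
             standardGeneric("evaluateModel"))
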