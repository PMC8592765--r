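# Condition helpers: every validated failure signals a classed condition so
# callers (and the CLI) can react without parsing messages.

dermError <- function(class, msg, ...) {
  stop(structure(class = c(class, "dermaseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

inputError      <- function(msg, ...) dermError("dermaseg_input_error", msg, ...)
validationError <- function(msg, ...) dermError("dermaseg_validation_error", msg, ...)
configError     <- function(msg, ...) dermError("dermaseg_config_error", msg, ...)
sizeError       <- function(msg, ...) dermError("dermaseg_size_error", msg, ...)
ambiguityError  <- function(msg, ...) dermError("dermaseg_ambiguity_error", msg, ...)
degenerateInputError <- function(msg, ...) dermError("dermaseg_degenerate_input_error", msg, ...)
undefinedMetricError <- function(msg, ...) dermError("dermaseg_undefined_metric_error", msg, ...)
divergenceError <- function(msg, ...) dermError("dermaseg_divergence_error", msg, ...)

clamp01 <- function(x) pmin(pmax(x, 0), 1)
clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Derive a bounded positive integer seed for a substream. Stays below 2^31.
substreamSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483399) + 1L
}

#' @useDynLib dermaseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
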