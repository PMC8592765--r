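# Image normalisation chain and joint image/mask augmentation.
#
# Chain order used throughout the package: gray-world colour constancy ->
# resize/augment -> ImageNet channel-mean subtraction -> scale to unit range.

IMAGENET_MEANS <- c(123.68, 116.779, 103.939)

#' ImageNet RGB channel means (0--255 scale)
#'
#' The channel means conventionally subtracted before feeding images to
#' encoders whose weights were conceived for ImageNet-preprocessed input.
#' @return numeric(3): R, G, B means.
#' @export
imagenetChannelMeans <- function() IMAGENET_MEANS

#' Gray-world colour constancy normalisation
#'
#' Rescales each channel by the gain \eqn{g_c = \bar\mu / \mu_c}, where
#' \eqn{\mu_c} is the channel mean and \eqn{\bar\mu} the mean of the three
#' channel means, so that (ignoring clipping) all channel means equal
#' \eqn{\bar\mu}. Output is clipped to [0, 255]. This evens out the colour
#' cast of varying illumination, a standard first step in dermoscopy
#' pipelines.
#'
#' @param image H x W x 3 array on the 0--255 scale; every channel must have
#'   a strictly positive mean.
#' @return The normalised H x W x 3 array.
#' @examples
#' img <- array(rep(c(100, 150, 200), each = 64 * 64), c(64, 64, 3))
#' range(grayWorldNormalize(img))  # all 150
#' @export
grayWorldNormalize <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    validationError("image must be H x W x 3")
  mu <- c(mean(image[, , 1]), mean(image[, , 2]), mean(image[, , 3]))
  if (any(mu <= 0))
    degenerateInputError(sprintf(
      "gray-world undefined: channel mean(s) not strictly positive (%s)",
      paste(signif(mu, 4), collapse = ", ")))
  g <- mean(mu) / mu
  out <- image
  for (c in 1:3) out[, , c] <- image[, , c] * g[c]
  clamp255(out)
}

#' Subtract fixed channel means
#'
#' @param image H x W x 3 array.
#' @param means numeric(3); defaults to [imagenetChannelMeans()].
#' @return H x W x 3 array; values may be negative (no clipping).
#' @export
subtractChannelMeans <- function(image, means = imagenetChannelMeans()) {
  out <- image
  for (c in 1:3) out[, , c] <- image[, , c] - means[c]
  out
}

# --- EBImage bridges (package convention: H x W[, C]; EBImage: x = width) ---

ebImg <- function(a) {
  if (is.matrix(a)) EBImage::Image(t(a))
  else EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
}
unEb <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

# Bilinear resize of an image (0..255) to target (H, W).
resizeImage <- function(image, targetHW) {
  unEb(EBImage::resize(ebImg(image), w = targetHW[2], h = targetHW[1],
                       filter = "bilinear"))
}

# Masks share the image interpolator and are re-binarised at 0.5, so that a
# mask and an identically warped image agree after thresholding.
resizeMask <- function(mask, targetHW) {
  m <- unEb(EBImage::resize(ebImg(mask), w = targetHW[2], h = targetHW[1],
                            filter = "bilinear"))
  (m > 0.5) * 1
}

#' Resize an image/mask pair to a stride-compatible resolution
#'
#' Bilinear resampling for the image; the mask is bilinearly warped and
#' re-thresholded at 0.5, which keeps it binary and consistent with the
#' image warp. Targets must be multiples of 32: the deepest encoder level
#' sits at stride 32, so other sizes cannot flow through the network.
#'
#' @param sample a [DermoscopySample-class].
#' @param target integer(2) `(H, W)`, each a multiple of 32 and >= 32.
#' @return The resized [DermoscopySample-class].
#' @export
resizePair <- function(sample, target) {
  target <- as.integer(target)
  if (length(target) == 1L) target <- rep(target, 2L)
  if (any(target < 32L) || any(target %% 32L != 0L))
    validationError(sprintf(
      "target (%s) must be multiples of 32 (encoder stride budget)",
      paste(target, collapse = "x")))
  dermoscopySample(sampleId(sample),
                   resizeImage(sampleImage(sample), target),
                   resizeMask(sampleMask(sample), target),
                   sampleSource(sample))
}

# --- HSV helpers (h in degrees 0..360, s,v in 0..1) ---

rgbToHsvArr <- function(image) {
  px <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  hsv
}

hsvToRgbArr <- function(hsv, dims) {
  h <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); tt <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, tt, v)))))
  g <- ifelse(i == 0, tt, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, tt,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dims)
  out[, , 1] <- r * 255; out[, , 2] <- g * 255; out[, , 3] <- b * 255
  out
}

# Center crop-or-pad to (H, W); zero padding.
centerFit <- function(x, targetHW) {
  grey <- is.matrix(x)
  d <- dim(x)[1:2]
  out <- if (grey) matrix(0, targetHW[1], targetHW[2])
         else array(0, c(targetHW, dim(x)[3]))
  sy <- max(0L, (d[1] - targetHW[1]) %/% 2L)
  sx <- max(0L, (d[2] - targetHW[2]) %/% 2L)
  oy <- max(0L, (targetHW[1] - d[1]) %/% 2L)
  ox <- max(0L, (targetHW[2] - d[2]) %/% 2L)
  ny <- min(d[1], targetHW[1]); nx <- min(d[2], targetHW[2])
  if (grey)
    out[oy + seq_len(ny), ox + seq_len(nx)] <-
      x[sy + seq_len(ny), sx + seq_len(nx)]
  else
    out[oy + seq_len(ny), ox + seq_len(nx), ] <-
      x[sy + seq_len(ny), sx + seq_len(nx), ]
  out
}

#' Apply a stochastic augmentation policy to an image/mask pair
#'
#' Geometric operations (scale, rotation, flips, crop) are applied with
#' identical parameters to image and mask; photometric operations
#' (brightness/contrast, CLAHE, HSV shifts) touch the image only. The mask
#' is warped with the same bilinear interpolator as the image and
#' re-thresholded at 0.5, so it stays binary and geometrically consistent
#' with the image. Draws from R's RNG: seed it (or pass `seed`) for
#' reproducible augmentation.
#'
#' @param sample a [DermoscopySample-class].
#' @param policy an [AugmentPolicy-class].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first.
#' @return The augmented [DermoscopySample-class].
#' @export
augmentSample <- function(sample, policy, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  img <- sampleImage(sample)
  # the mask travels through the geometric chain as a continuous field and
  # is thresholded once at the end, so that chained interpolations stay
  # consistent with the identically warped image
  msk <- sampleMask(sample) + 0
  d0 <- dim(msk)

  # scale (joint)
  if (policy@scaleRange[1] != 1 || policy@scaleRange[2] != 1) {
    s <- stats::runif(1, policy@scaleRange[1], policy@scaleRange[2])
    nd <- pmax(c(32L, 32L), as.integer(round(d0 * s)))
    img <- resizeImage(img, nd)
    msk <- unEb(EBImage::resize(ebImg(msk), w = nd[2], h = nd[1],
                                filter = "bilinear"))
    img <- centerFit(img, d0)
    msk <- centerFit(msk, d0)
  }
  # rotation (joint)
  if (policy@rotationRange[1] != 0 || policy@rotationRange[2] != 0) {
    ang <- stats::runif(1, policy@rotationRange[1], policy@rotationRange[2])
    img <- unEb(EBImage::rotate(ebImg(img), ang, filter = "bilinear",
                                output.dim = rev(d0), bg.col = 0))
    msk <- unEb(EBImage::rotate(ebImg(msk), ang, filter = "bilinear",
                                output.dim = rev(d0), bg.col = 0))
  }
  # flips (joint)
  if (policy@hflipProb > 0 && stats::runif(1) < policy@hflipProb) {
    img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (policy@vflipProb > 0 && stats::runif(1) < policy@vflipProb) {
    img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  # brightness / contrast (image only)
  if (any(policy@brightnessRange != 0) || any(policy@contrastRange != 0)) {
    b <- stats::runif(1, policy@brightnessRange[1], policy@brightnessRange[2])
    cfac <- 1 + stats::runif(1, policy@contrastRange[1],
                             policy@contrastRange[2])
    img <- clamp255((img - 127.5) * cfac + 127.5 + 255 * b)
  }
  # CLAHE (image only)
  if (policy@claheProb > 0 && stats::runif(1) < policy@claheProb) {
    eb <- ebImg(clamp255(img) / 255)
    eq <- EBImage::clahe(eb, nx = 4L, ny = 4L, limit = policy@claheClip)
    img <- clamp255(unEb(eq) * 255)
  }
  # HSV shifts (image only)
  if (any(policy@hsvShift != 0)) {
    dh <- stats::runif(1, -policy@hsvShift[1], policy@hsvShift[1]) / 360
    ds <- stats::runif(1, -policy@hsvShift[2], policy@hsvShift[2]) / 255
    dv <- stats::runif(1, -policy@hsvShift[3], policy@hsvShift[3]) / 255
    hsv <- rgbToHsvArr(clamp255(img))
    hsv[1, ] <- (hsv[1, ] + dh) %% 1
    hsv[2, ] <- clamp01(hsv[2, ] + ds)
    hsv[3, ] <- clamp01(hsv[3, ] + dv)
    img <- hsvToRgbArr(hsv, dim(img))
  }
  # random crop (joint)
  if (!anyNA(policy@cropSize)) {
    cs <- policy@cropSize
    d <- dim(msk)
    if (any(cs > d))
      sizeError(sprintf("crop %s exceeds image size %s",
                        paste(cs, collapse = "x"), paste(d, collapse = "x")))
    oy <- if (d[1] > cs[1]) sample.int(d[1] - cs[1] + 1L, 1L) - 1L else 0L
    ox <- if (d[2] > cs[2]) sample.int(d[2] - cs[2] + 1L, 1L) - 1L else 0L
    img <- img[oy + seq_len(cs[1]), ox + seq_len(cs[2]), , drop = FALSE]
    msk <- msk[oy + seq_len(cs[1]), ox + seq_len(cs[2]), drop = FALSE]
  }
  dermoscopySample(sampleId(sample), img, (msk > 0.5) * 1,
                   sampleSource(sample))
}

#' Derive the validation-time policy (crop only)
#'
#' Random cropping is the one augmentation also applied to validation
#' images (when `applyToValidation` is set); every other operation is
#' disabled.
#'
#' @param policy an [AugmentPolicy-class].
#' @return An [AugmentPolicy-class] retaining only the crop.
#' @export
validationPolicy <- function(policy) {
  p <- noAugmentPolicy()
  if (policy@applyToValidation) p@cropSize <- policy@cropSize
  p
}

# Full network-input transform for one already gray-world-normalised image.
networkInput <- function(image, means = imagenetChannelMeans()) {
  subtractChannelMeans(image, means) / 255
}
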