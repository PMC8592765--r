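# Seeded synthetic dermoscopy generator: a darker, irregular, star-convex
# lesion blob on a textured skin background with an illumination ramp,
# Gaussian noise and optional hair arcs (image only, never in the mask).
# Per-sample substreams are derived from the master seed by counter, so any
# sample can be regenerated independently.

# Rasterise a star-convex blob: centre (cy, cx), elliptical axes (a, b),
# orientation phi, radial modulation s(theta). Returns H x W {0,1}.
starBlobMask <- function(H, W, cy, cx, a, b, phi, harm, irr) {
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  dx <- X - cx
  dy <- Y - cy
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  u <- xr / a
  v <- yr / b
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  s <- rep(1, length(theta))
  if (irr > 0) {
    for (k in seq_len(nrow(harm))) {
      kk <- k + 1L
      s <- s + irr * (harm[k, 1] * cos(kk * theta) +
                      harm[k, 2] * sin(kk * theta)) / kk
    }
  }
  s <- pmin(pmax(s, 0.3), 1.6)
  m <- matrix(as.numeric(rho <= s), H, W)
  m
}

#' Generate one synthetic dermoscopy sample
#'
#' Background: a skin-tone base colour plus a linear illumination ramp,
#' low-frequency texture and Gaussian pixel noise. Lesion: a star-convex
#' blob whose radius is an ellipse modulated by a low-order random harmonic
#' series scaled by `boundaryIrregularity` (0 gives a pure ellipse), filled
#' with a darkened, texture-perturbed colour; the mask is the exact blob
#' indicator. Optional thin dark arcs emulate hairs and are drawn on the
#' image only. The blob is rescaled against its measured pixel area so the
#' mask area fraction always falls inside `lesionAreaRange`.
#'
#' @param config a [SyntheticConfig-class].
#' @param index sample counter (>= 1); `config@seed` and `index` define the
#'   substream, so calls are reproducible and order-independent.
#' @return A [DermoscopySample-class] with `source = "synthetic"`. The mask
#'   carries a `"geometry"` attribute (centre, axes, orientation, target
#'   fraction) for diagnostics.
#' @examples
#' s <- generateSample(syntheticConfig(seed = 3), index = 1)
#' mean(sampleMask(s))
#' @export
generateSample <- function(config, index = 1L) {
  validObject(config)
  set.seed(substreamSeed(config@seed, index))
  H <- config@size[1]; W <- config@size[2]
  lo <- config@lesionAreaRange[1]; hi <- config@lesionAreaRange[2]
  irr <- config@boundaryIrregularity

  mask <- NULL
  geom <- NULL
  for (try in 1:20) {
    f <- stats::runif(1, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
    targetA <- f * H * W
    q <- stats::runif(1, 0.6, 1)
    a <- sqrt(targetA / (pi * q))
    b <- q * a
    phi <- stats::runif(1, 0, pi)
    cy <- stats::runif(1, 0.42, 0.58) * H
    cx <- stats::runif(1, 0.42, 0.58) * W
    harm <- matrix(stats::rnorm(8), 4, 2)
    # calibrate the axes against the measured pixel area
    for (iter in 1:4) {
      m <- starBlobMask(H, W, cy, cx, a, b, phi, harm, irr)
      area <- sum(m)
      if (area < 4) break
      t <- sqrt(targetA / area)
      if (abs(t - 1) < 0.005) break
      a <- a * t
      b <- b * t
    }
    m <- starBlobMask(H, W, cy, cx, a, b, phi, harm, irr)
    area <- sum(m)
    if (area >= 4 && area / (H * W) >= lo && area / (H * W) <= hi) {
      mask <- m
      geom <- list(cy = cy, cx = cx, a = a, b = b, phi = phi,
                   targetFraction = f)
      break
    }
  }
  if (is.null(mask))
    configError(sprintf(
      "could not realise a lesion with area fraction in [%g, %g] at %dx%d",
      lo, hi, H, W))

  base <- c(205, 160, 140) + stats::runif(3, -15, 15)
  psi <- stats::runif(1, 0, 2 * pi)
  Xn <- matrix(rep(seq_len(W), each = H), H, W) / W - 0.5
  Yn <- matrix(rep(seq_len(H), W), H, W) / H - 0.5
  ramp <- config@illuminationGradient * 255 *
    (cos(psi) * Xn + sin(psi) * Yn)
  fx <- stats::runif(1, 1, 4); fy <- stats::runif(1, 1, 4)
  ph <- stats::runif(1, 0, 2 * pi)
  texture <- (config@noiseSd / 2) * sin(2 * pi * (fx * Xn + fy * Yn) + ph)
  lesionFac <- (1 - config@lesionContrast) * c(1, 0.85, 0.8)

  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    plane <- base[ch] * (1 - mask) + base[ch] * lesionFac[ch] * mask
    plane <- plane + ramp + texture +
      stats::rnorm(H * W, sd = config@noiseSd)
    img[, , ch] <- plane
  }

  if (config@hairProbability > 0 &&
      stats::runif(1) < config@hairProbability) {
    nh <- sample.int(4L, 1L)
    for (hh in seq_len(nh)) {
      p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      p1 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      p2 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      dark <- stats::runif(1, 20, 60)
      tt <- seq(0, 1, length.out = 4L * max(H, W))
      py <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
      px <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
      iy <- round(py); ix <- round(px)
      ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[cbind(iy[ok], ix[ok])] <- dark
        img[, , ch] <- pl
      }
    }
  }
  img <- round(clamp255(img))
  attr(mask, "geometry") <- geom
  dermoscopySample(sprintf("SYN_%04d", index), img, mask, "synthetic")
}

#' Generate a list of synthetic samples in memory
#'
#' @param config a [SyntheticConfig-class].
#' @param indices which sample counters to realise (default
#'   `1:config@nSamples`).
#' @return list of [DermoscopySample-class].
#' @export
generateSamples <- function(config, indices = seq_len(config@nSamples)) {
  lapply(indices, function(i) generateSample(config, i))
}

#' Generate and write a synthetic dataset in an on-disk dialect
#'
#' Writes `nSamples` image/mask pairs in the chosen layout: `"isic"` (flat
#' `<id>.png` + `<id>_segmentation.png`; PNG keeps round trips bit-exact)
#' or `"ph2"` (per-case directory with `<id>.bmp` and `<id>_lesion.bmp`).
#' A `manifest.tsv` (sample_id, image, mask) is written alongside. Reading
#' the files back through [readIsicPair()] / [readPh2Case()] reproduces the
#' in-memory samples exactly.
#'
#' @param config a [SyntheticConfig-class].
#' @param layout `"isic"` or `"ph2"`.
#' @param outDir output directory; must be empty unless `overwrite`.
#' @param overwrite allow writing into a non-empty directory.
#' @return data.frame manifest (`sample_id`, `image`, `mask`), invisibly.
#' @export
generateDataset <- function(config, layout = c("isic", "ph2"), outDir,
                            overwrite = FALSE) {
  layout <- match.arg(layout)
  if (dir.exists(outDir) && length(list.files(outDir)) > 0L && !overwrite)
    inputError(sprintf(
      "output directory '%s' is not empty (use overwrite = TRUE)", outDir))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(config@nSamples), function(i) {
    s <- generateSample(config, i)
    p <- writeSamplePair(s, layout, outDir)
    data.frame(sample_id = sampleId(s), image = p[["image"]],
               mask = p[["mask"]])
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
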