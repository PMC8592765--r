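# Readers/writers for the two on-disk dialects (ISIC-2018-style flat pairs,
# PH2-style per-case directories) and the split manifest.

# Read any supported raster to H x W x C (or H x W) doubles on 0..255.
readRaster <- function(path) {
  if (!file.exists(path))
    inputError(sprintf("file does not exist: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(readBMP(path))
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)  # x (width) first
  a <- a * 255
  if (length(dim(a)) == 2L) t(a)
  else aperm(a, c(2L, 1L, 3L))
}

writeRaster <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(writeBMP(x, path))
  a <- if (is.matrix(x)) t(x) / 255 else aperm(x, c(2L, 1L, 3L)) / 255
  a <- pmin(pmax(a, 0), 1)
  img <- EBImage::Image(a, colormode = if (is.matrix(x)) "Grayscale" else "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

# Collapse a mask raster to one channel and binarise on the 8-bit scale:
# values > 127 map to 1, everything else to 0 (tolerates anti-aliased or
# JPEG-fringed mask boundaries).
collapseMask <- function(m, path = "<mask>") {
  if (!is.matrix(m)) {
    nc <- dim(m)[3]
    first <- m[, , 1]
    for (k in seq_len(nc)[-1]) {
      if (!isTRUE(all.equal(m[, , k], first, tolerance = 1e-8)))
        validationError(sprintf(
          "mask '%s' has %d differing channels; cannot collapse", path, nc))
    }
    m <- first
  }
  (m > 127) * 1
}

#' Read an ISIC-style image/mask pair
#'
#' Reads a dermoscopic image and its segmentation mask from two files
#' (ISIC-2018 layout: `<id>.jpg`/`<id>.png` plus `<id>_segmentation.png`).
#' The mask is collapsed to one channel if its channels are identical and
#' binarised with the 8-bit rule `value > 127 -> 1`. The sample id is the
#' image filename stem (with any `_segmentation` suffix stripped).
#'
#' @param imagePath path to the RGB image (JPEG/PNG/TIFF/BMP).
#' @param maskPath path to the mask raster (PNG/BMP/...).
#' @return A [DermoscopySample-class] with `source = "isic"`.
#' @examples
#' cfg <- syntheticConfig(nSamples = 1L, seed = 7L)
#' d <- file.path(tempdir(), "isic-demo")
#' man <- generateDataset(cfg, layout = "isic", outDir = d, overwrite = TRUE)
#' s <- readIsicPair(man$image[1], man$mask[1])
#' @export
readIsicPair <- function(imagePath, maskPath) {
  img <- readRaster(imagePath)
  msk <- readRaster(maskPath)
  if (is.matrix(img))
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  mdim <- if (is.matrix(msk)) dim(msk) else dim(msk)[1:2]
  if (!identical(dim(img)[1:2], mdim))
    validationError(sprintf(
      "image (%s) and mask (%s) shapes differ for '%s'",
      paste(dim(img)[1:2], collapse = "x"), paste(mdim, collapse = "x"),
      imagePath))
  id <- sub("_segmentation$", "",
            tools::file_path_sans_ext(basename(imagePath)))
  dermoscopySample(id, img, collapseMask(msk, maskPath), "isic")
}

#' Read a PH2-style case directory
#'
#' A PH2-style case is a directory holding one dermoscopic image and one
#' lesion mask whose filename contains `_lesion` (BMP in the original
#' distribution; any supported raster works). Nested subdirectories are
#' searched. The case directory name becomes the sample id.
#'
#' @param caseDir path to the case directory.
#' @return A [DermoscopySample-class] with `source = "ph2"`.
#' @export
readPh2Case <- function(caseDir) {
  if (!dir.exists(caseDir))
    inputError(sprintf("case directory does not exist: '%s'", caseDir))
  files <- list.files(caseDir, recursive = TRUE, full.names = TRUE)
  rasters <- files[tolower(tools::file_ext(files)) %in%
                     c("bmp", "png", "jpg", "jpeg", "tif", "tiff")]
  maskFiles <- rasters[grepl("_lesion", basename(rasters))]
  imgFiles <- setdiff(rasters, maskFiles)
  if (length(maskFiles) != 1L)
    ambiguityError(sprintf(
      "expected exactly one '_lesion' mask in '%s'; found %d (%s)",
      caseDir, length(maskFiles),
      paste(basename(maskFiles), collapse = ", ")))
  if (length(imgFiles) != 1L)
    ambiguityError(sprintf(
      "expected exactly one dermoscopic image in '%s'; found %d (%s)",
      caseDir, length(imgFiles), paste(basename(imgFiles), collapse = ", ")))
  img <- readRaster(imgFiles)
  msk <- readRaster(maskFiles)
  if (is.matrix(img))
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  mdim <- if (is.matrix(msk)) dim(msk) else dim(msk)[1:2]
  if (!identical(dim(img)[1:2], mdim))
    validationError(sprintf(
      "image (%s) and mask (%s) shapes differ in '%s'",
      paste(dim(img)[1:2], collapse = "x"), paste(mdim, collapse = "x"),
      caseDir))
  dermoscopySample(basename(normalizePath(caseDir)), img,
                   collapseMask(msk, maskFiles), "ph2")
}

# Write one sample in a dialect; returns c(image=, mask=) paths.
writeSamplePair <- function(sample, layout, outDir) {
  id <- sampleId(sample)
  if (layout == "isic") {
    ip <- file.path(outDir, paste0(id, ".png"))
    mp <- file.path(outDir, paste0(id, "_segmentation.png"))
    writeRaster(sampleImage(sample), ip)
    writeRaster(sampleMask(sample) * 255, mp)
  } else {
    d <- file.path(outDir, id)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    ip <- file.path(d, paste0(id, ".bmp"))
    mp <- file.path(d, paste0(id, "_lesion.bmp"))
    writeRaster(sampleImage(sample), ip)
    writeRaster(sampleMask(sample) * 255, mp)
  }
  c(image = ip, mask = mp)
}

#' Read every sample of an on-disk dataset
#'
#' @param dir dataset directory.
#' @param layout `"isic"` (flat `<id>` + `<id>_segmentation` pairs) or
#'   `"ph2"` (per-case directories).
#' @return list of [DermoscopySample-class].
#' @export
readDataset <- function(dir, layout = c("isic", "ph2")) {
  layout <- match.arg(layout)
  if (!dir.exists(dir)) inputError(sprintf("no such directory: '%s'", dir))
  if (layout == "isic") {
    masks <- list.files(dir, pattern = "_segmentation\\.[A-Za-z]+$",
                        full.names = TRUE)
    lapply(masks, function(mp) {
      stem <- sub("_segmentation\\.[A-Za-z]+$", "", basename(mp))
      imgs <- list.files(dir, pattern = paste0("^", stem, "\\.[A-Za-z]+$"),
                         full.names = TRUE)
      if (length(imgs) != 1L)
        ambiguityError(sprintf("no unique image for mask '%s'", mp))
      readIsicPair(imgs, mp)
    })
  } else {
    cases <- list.dirs(dir, recursive = FALSE)
    lapply(cases, readPh2Case)
  }
}

#' Write / read a split manifest
#'
#' The manifest is a two-column tab-separated table (`sample_id`, `subset`)
#' with one row per sample, `subset` in train/validation/test.
#'
#' @param split a [DatasetSplit-class].
#' @param path file path.
#' @return `writeSplitManifest`: the path, invisibly;
#'   `readSplitManifest`: a [DatasetSplit-class].
#' @export
writeSplitManifest <- function(split, path) {
  df <- data.frame(
    sample_id = c(split@train, split@validation, split@test),
    subset = rep(c("train", "validation", "test"),
                 c(length(split@train), length(split@validation),
                   length(split@test))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSplitManifest
#' @export
readSplitManifest <- function(path) {
  if (!file.exists(path)) inputError(sprintf("no such manifest: '%s'", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  new("DatasetSplit",
      train = df$sample_id[df$subset == "train"],
      validation = df$sample_id[df$subset == "validation"],
      test = df$sample_id[df$subset == "test"])
}
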