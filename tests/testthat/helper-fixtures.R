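# Shared fixtures, all generated in code.

# deterministic sample with a rectangular lesion
toySample <- function(H = 64L, W = 64L, id = "toy") {
  img <- array(0, c(H, W, 3))
  img[, , 1] <- 180; img[, , 2] <- 140; img[, , 3] <- 120
  msk <- matrix(0, H, W)
  msk[(H %/% 4):(H %/% 2), (W %/% 4):(W %/% 2)] <- 1
  for (c in 1:3) img[, , c] <- img[, , c] - 60 * msk
  dermoscopySample(id, img, msk, "synthetic")
}

randomImage <- function(H = 64L, W = 64L, lo = 50, hi = 150) {
  array(stats::runif(H * W * 3, lo, hi), c(H, W, 3))
}

tinySpec <- function(...) {
  modelSpec("unet", "plain", baseWidth = 4L, dropoutRate = 0, ...)
}

quickTrainData <- function(n = 8L, seed = 5L, size = 64L) {
  cfg <- syntheticConfig(nSamples = n, size = c(size, size), seed = seed)
  generateSamples(cfg)
}
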