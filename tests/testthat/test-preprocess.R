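# Gray-world normalisation, mean subtraction, resizing and joint
# image/mask augmentation.

test_that("gray-world gains equalise channel means", {
  img <- array(0, c(64, 64, 3))
  img[, , 1] <- 100; img[, , 2] <- 150; img[, , 3] <- 200
  out <- grayWorldNormalize(img)
  expect_equal(range(out[, , 1]), c(150, 150))
  expect_equal(range(out[, , 2]), c(150, 150))
  expect_equal(range(out[, , 3]), c(150, 150))

  # already balanced image is returned unchanged
  set.seed(1)
  bal <- randomImage()
  mu <- mean(bal)
  for (c in 1:3) bal[, , c] <- bal[, , c] - mean(bal[, , c]) + mu
  expect_equal(grayWorldNormalize(bal), bal, tolerance = 1e-12)

  zero <- img
  zero[, , 2] <- 0
  expect_error(grayWorldNormalize(zero),
               class = "dermaseg_degenerate_input_error")
})

test_that("gray-world channel means agree within 1e-6 relative when no clipping", {
  set.seed(42)
  for (i in 1:25) {
    img <- randomImage(48, 48, lo = 40, hi = 160)
    out <- grayWorldNormalize(img)
    expect_true(max(out) < 255 && min(out) > 0)  # no clipping occurred
    mus <- c(mean(out[, , 1]), mean(out[, , 2]), mean(out[, , 3]))
    expect_lt(diff(range(mus)) / mean(mus), 1e-6)
  }
})

test_that("channel-mean subtraction is exact and linear", {
  img <- array(150, c(32, 32, 3))
  out <- subtractChannelMeans(img)
  expect_equal(unique(as.vector(out[, , 1])), 150 - 123.68)
  expect_equal(unique(as.vector(out[, , 2])), 150 - 116.779)
  expect_equal(unique(as.vector(out[, , 3])), 150 - 103.939)
  expect_identical(subtractChannelMeans(img, c(0, 0, 0)), img)
  m <- c(10, 20, 30)
  expect_equal(subtractChannelMeans(subtractChannelMeans(img, m), m),
               subtractChannelMeans(img, 2 * m))
})

test_that("resizePair enforces the stride budget and keeps masks binary", {
  s <- toySample(96, 96)
  r <- resizePair(s, c(64, 64))
  expect_equal(dim(sampleImage(r)), c(64L, 64L, 3L))
  expect_equal(dim(sampleMask(r)), c(64L, 64L))
  expect_true(all(sampleMask(r) %in% c(0, 1)))
  err <- expect_error(resizePair(s, c(50, 64)),
                      class = "dermaseg_validation_error")
  expect_match(conditionMessage(err), "32")

  # constant-region idempotence: up then down leaves the mask unchanged
  up <- resizePair(s, c(192, 192))
  back <- resizePair(up, c(96, 96))
  expect_equal(sampleMask(back), sampleMask(s))
})

test_that("flips mirror image and mask jointly and preserve lesion area", {
  s <- toySample()
  pol <- noAugmentPolicy()
  pol@hflipProb <- 1
  a <- augmentSample(s, pol, seed = 1)
  expect_equal(sampleMask(a), sampleMask(s)[, 64:1])
  expect_equal(sampleImage(a), sampleImage(s)[, 64:1, ])
  expect_equal(sum(sampleMask(a)), sum(sampleMask(s)))
})

test_that("photometric-only policies never touch the mask", {
  s <- toySample()
  pol <- augmentPolicy(scaleRange = c(1, 1), rotationRange = c(0, 0),
                       hflipProb = 0, vflipProb = 0, cropSize = NA)
  for (seed in 1:5) {
    a <- augmentSample(s, pol, seed = seed)
    expect_identical(sampleMask(a), sampleMask(s))
    expect_true(all(sampleMask(a) %in% c(0, 1)))
  }
})

test_that("augmentation is deterministic under a fixed seed", {
  s <- toySample()
  pol <- augmentPolicy(cropSize = 64L)
  a1 <- augmentSample(s, pol, seed = 99)
  a2 <- augmentSample(s, pol, seed = 99)
  expect_identical(sampleImage(a1), sampleImage(a2))
  expect_identical(sampleMask(a1), sampleMask(a2))
})

test_that("augmentation preserves shape equality and mask binarity", {
  cfg <- syntheticConfig(seed = 8)
  pol <- augmentPolicy(cropSize = 64L)
  for (i in 1:5) {
    s <- generateSample(cfg, i)
    a <- augmentSample(s, pol, seed = i)
    expect_equal(dim(sampleImage(a))[1:2], dim(sampleMask(a)))
    expect_true(all(sampleMask(a) %in% c(0, 1)))
  }
})

test_that("geometric ops keep image and mask consistent (image == mask)", {
  # image replicating the mask in all channels; geometric-only policy:
  # thresholding the warped image must reproduce the warped mask
  msk <- sampleMask(generateSample(syntheticConfig(seed = 3), 1))
  img <- array(rep(msk * 255, 3L), c(dim(msk), 3L))
  s <- dermoscopySample("geo", img, msk, "synthetic")
  pol <- augmentPolicy(hflipProb = 0.5, vflipProb = 0.5,
                       brightnessRange = c(0, 0), contrastRange = c(0, 0),
                       claheProb = 0, hsvShift = c(0, 0, 0), cropSize = 64L)
  for (seed in 1:6) {
    a <- augmentSample(s, pol, seed = seed)
    thresh <- (sampleImage(a)[, , 1] > 127.5) * 1
    expect_equal(thresh, sampleMask(a))
  }
})

test_that("crops larger than the image are rejected", {
  s <- toySample()
  pol <- noAugmentPolicy()
  pol@cropSize <- c(128L, 128L)
  expect_error(augmentSample(s, pol, seed = 1),
               class = "dermaseg_size_error")
})

test_that("validationPolicy keeps only the crop", {
  pol <- augmentPolicy(cropSize = 32L, applyToValidation = TRUE)
  vp <- validationPolicy(pol)
  expect_equal(vp@cropSize, c(32L, 32L))
  expect_equal(vp@hflipProb, 0)
  expect_equal(vp@scaleRange, c(1, 1))
  polNo <- augmentPolicy(cropSize = 32L, applyToValidation = FALSE)
  expect_true(anyNA(validationPolicy(polNo)@cropSize))
})
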