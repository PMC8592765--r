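# Architecture contracts: shapes, pyramid, parameter counting, determinism
# and gradient flow.

test_that("logit shape equals input shape across architectures", {
  set.seed(2)
  x64 <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  x96 <- array(rnorm(96 * 96 * 3), c(96, 96, 3))
  m1 <- buildModel(tinySpec(), initSeed = 1)
  expect_equal(dim(modelForward(m1, list(x64))[[1]]), c(64L, 64L))
  m2 <- buildModel(modelSpec("unetpp_improved", "efficientnet_b0",
                             decoderWidths = c(4, 8, 8, 8, 8),
                             dropoutRate = 0), initSeed = 1)
  expect_equal(dim(modelForward(m2, list(x96))[[1]]), c(96L, 96L))
  x50 <- array(0, c(50, 50, 3))
  expect_error(modelForward(m1, list(x50)),
               class = "dermaseg_validation_error")
})

test_that("plain encoder follows the channel-doubling rule", {
  m <- buildModel(modelSpec("unet", "plain", baseWidth = 8L,
                            dropoutRate = 0), initSeed = 1)
  expect_equal(m@tapChannels, c(8L, 16L, 32L, 64L, 128L))
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  fp <- encoderFeatures(m, list(x))
  expect_equal(vapply(fp$maps, function(a) dim(a)[2], integer(1)),
               c(8L, 16L, 32L, 64L, 128L))
  expect_equal(fp$strides, c(1L, 2L, 4L, 8L, 16L))
})

test_that("EfficientNet-B0 pyramid has the canonical strides and channels", {
  m <- buildModel(modelSpec("unetpp_improved", "efficientnet_b0",
                            decoderWidths = c(4, 4, 4, 4, 4),
                            dropoutRate = 0), initSeed = 1)
  x <- array(rnorm(256 * 256 * 3) * 0.1, c(256, 256, 3))
  fp <- encoderFeatures(m, list(x))
  expect_equal(fp$channels, c(16L, 24L, 40L, 112L, 320L))
  expect_equal(fp$strides, c(2L, 4L, 8L, 16L, 32L))
  spat <- vapply(fp$maps, function(a) dim(a)[3], integer(1))
  expect_equal(spat, c(128L, 64L, 32L, 16L, 8L))
  chan <- vapply(fp$maps, function(a) dim(a)[2], integer(1))
  expect_equal(chan, c(16L, 24L, 40L, 112L, 320L))
})

test_that("improved decoder has strictly fewer parameters than dense", {
  for (enc in c("plain", "efficientnet_b0")) {
    sImp <- modelSpec("unetpp_improved", enc, baseWidth = 8L)
    sDen <- modelSpec("unetpp_dense", enc, baseWidth = 8L)
    nImp <- countTrainableParameters(buildModel(sImp, 1))
    nDen <- countTrainableParameters(buildModel(sDen, 1))
    expect_lt(nImp, nDen)
  }
})

test_that("parameter count is invariant to input size and counts affine BN", {
  m <- buildModel(tinySpec(), initSeed = 1)
  n1 <- countTrainableParameters(m)
  for (sz in c(64L, 96L)) {
    x <- array(0, c(sz, sz, 3))
    invisible(modelForward(m, list(x)))
    expect_identical(countTrainableParameters(m), n1)
  }
  # independent arithmetic oracle for the classic plain U-Net:
  # two 3x3 conv(+bias) per level with BN pairs, transposed-conv ups
  # (bias, no BN), 1x1 head
  base <- 4L
  ch <- base * 2^(0:4)
  convP <- function(ci, co) ci * co * 9 + co
  enc <- convP(3, ch[1]) + convP(ch[1], ch[1])
  for (i in 2:5) enc <- enc + convP(ch[i - 1], ch[i]) + convP(ch[i], ch[i])
  bn <- 2 * (2 * sum(ch))                     # encoder BN pairs
  dec <- 0
  for (i in 4:1) {
    dec <- dec + ch[i + 1] * ch[i] * 4 + ch[i] +      # transposed conv
      convP(2 * ch[i], ch[i]) + convP(ch[i], ch[i]) + # double conv
      2 * (2 * ch[i])                                 # their BN pairs
  }
  head <- ch[1] + 1
  expect_identical(n1, as.numeric(enc + bn + dec + head))
})

test_that("deep supervision adds heads at every decoder column", {
  sOne <- modelSpec("unetpp_improved", "plain", baseWidth = 4L,
                    decoderWidths = c(4, 8, 16, 32, 64), dropoutRate = 0)
  sDS <- sOne
  sDS@deepSupervision <- TRUE
  mOne <- buildModel(sOne, 1)
  mDS <- buildModel(sDS, 1)
  expect_length(mOne@outputNodes, 1L)
  expect_length(mDS@outputNodes, 4L)
  # three extra 1x1 heads on 4-channel nodes: 3 * (4 + 1) parameters
  expect_equal(countTrainableParameters(mDS) -
                 countTrainableParameters(mOne), 15)
})

test_that("evaluation-mode forward is deterministic", {
  m <- buildModel(modelSpec("unetpp_improved", "efficientnet_b0",
                            decoderWidths = c(4, 4, 4, 4, 4)), initSeed = 7)
  set.seed(1)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  z1 <- modelForward(m, list(x))
  z2 <- modelForward(m, list(x))
  expect_identical(z1, z2)
})

test_that("one optimiser step on a batch reduces the training loss", {
  m <- buildModel(tinySpec(), initSeed = 3)
  set.seed(9)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  y <- matrix(0, 64, 64); y[10:40, 10:40] <- 1
  b <- dermaseg:::imagesToBatch(list(x))
  yv <- dermaseg:::masksToBatch(list(y))
  step <- function(lr) dermaseg:::eng_train_step(m@ptr, b$x,
    as.integer(b$dims), yv, 0.5, lr, 0.9, 0.999, 1e-8)$loss
  l0 <- step(1e-3)  # loss before this update
  l1 <- step(0)     # loss after it
  expect_lt(l1, l0)
})

test_that("weights round-trip through checkpoints exactly", {
  m <- buildModel(tinySpec(), initSeed = 4)
  w <- getWeights(m)
  p <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, p)
  ck <- loadCheckpoint(p)
  m2 <- restoreModel(ck)
  expect_identical(getWeights(m2), w)
  set.seed(2)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  expect_identical(modelForward(m, list(x)), modelForward(m2, list(x)))
})

test_that("unknown enum values are rejected at spec construction", {
  expect_error(modelSpec("segnet", "plain"), "architecture")
  expect_error(modelSpec("unet", "resnet"), "encoder")
  expect_error(modelSpec("unet", "plain", activation = "tanh"), "activation")
  expect_error(buildModel(modelSpec(encoderPretrained = TRUE)),
               class = "dermaseg_config_error")
})
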