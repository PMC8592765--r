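# Training loop, checkpointing, evaluation and reporting.

test_that("training returns one record per epoch and the best checkpoint", {
  samples <- quickTrainData(n = 10L, seed = 5L)
  m <- buildModel(tinySpec(), initSeed = 1)
  tc <- trainingConfig(epochs = 2L, seed = 3L, learningRate = 1e-3)
  fit <- trainModel(m, samples[1:8], samples[9:10], tc)
  expect_s4_class(fit, "TrainingResult")
  expect_equal(nrow(fit@history), 2L)
  expect_equal(fit@history$epoch, 1:2)
  expect_equal(fit@bestEpoch, which.min(fit@history$val_loss))
  # checkpoint optimality: no epoch beats the checkpoint on val_loss
  expect_true(all(fit@history$val_loss >=
                    fit@history$val_loss[fit@bestEpoch]))
  expect_true(all(is.finite(fit@history$train_loss)))
  expect_true(all(fit@history$val_dice >= 0 & fit@history$val_dice <= 1))
})

test_that("empty datasets are rejected", {
  samples <- quickTrainData(n = 2L)
  m <- buildModel(tinySpec(), initSeed = 1)
  tc <- trainingConfig(epochs = 1L, seed = 1L)
  expect_error(trainModel(m, list(), samples, tc),
               class = "dermaseg_input_error")
  expect_error(trainModel(m, samples, list(), tc),
               class = "dermaseg_input_error")
})

test_that("reported batch loss equals the combined loss recomputed in R", {
  samples <- quickTrainData(n = 2L, seed = 6L)
  m <- buildModel(tinySpec(), initSeed = 2)  # dropout 0: deterministic
  alpha <- 0.3
  xs <- lapply(samples, function(s)
    dermaseg:::networkInput(grayWorldNormalize(sampleImage(s))))
  ys <- lapply(samples, sampleMask)
  b <- dermaseg:::imagesToBatch(xs)
  yv <- dermaseg:::masksToBatch(ys)
  # logits of the same train-mode forward the step performs
  z <- dermaseg:::eng_forward(m@ptr, b$x, as.integer(b$dims), TRUE)
  p <- 1 / (1 + exp(-as.numeric(z)))
  expected <- combinedLoss(p, yv, alpha)  # sums are order-invariant
  got <- dermaseg:::eng_train_step(m@ptr, b$x, as.integer(b$dims), yv,
                                   alpha, 1e-4, 0.9, 0.999, 1e-8)
  expect_equal(got$loss, expected, tolerance = 1e-4)
})

test_that("training histories are bitwise identical for the same seed", {
  samples <- quickTrainData(n = 8L, seed = 8L)
  tc <- trainingConfig(epochs = 2L, seed = 42L, learningRate = 1e-3)
  pol <- augmentPolicy(cropSize = 64L)
  runOnce <- function() {
    m <- buildModel(modelSpec("unet", "plain", baseWidth = 4L,
                              dropoutRate = 0.2), initSeed = 7)
    trainModel(m, samples[1:6], samples[7:8], tc, augment = pol)
  }
  f1 <- runOnce()
  f2 <- runOnce()
  expect_identical(f1@history, f2@history)
  expect_identical(f1@checkpoint, f2@checkpoint)
  expect_identical(f1@bestEpoch, f2@bestEpoch)
})

test_that("an oracle predictor scores perfectly; a constant one scores zero", {
  samples <- quickTrainData(n = 4L, seed = 9L)
  oracle <- function(imgs) {
    lapply(seq_along(imgs), function(i) sampleMask(samples[[i]]) * 0.98 + 0.01)
  }
  ev <- evaluateModel(oracle, samples)
  expect_equal(unname(ev@summary["dice"]), 1)
  expect_equal(unname(ev@summary["iou"]), 1)
  expect_equal(unname(ev@summary["accuracy"]), 1)

  background <- function(imgs)
    lapply(imgs, function(im) matrix(0.01, nrow(im), ncol(im)))
  evBg <- evaluateModel(background, samples)
  expect_equal(unname(evBg@summary["dice"]), 0)
  bgFrac <- mean(vapply(samples, function(s) mean(sampleMask(s) == 0),
                        numeric(1)))
  expect_equal(unname(evBg@summary["accuracy"]), bgFrac)
})

test_that("the dataset summary is the unweighted mean of per-image rows", {
  samples <- quickTrainData(n = 3L, seed = 10L)
  half <- function(imgs)
    lapply(seq_along(imgs), function(i) {
      m <- sampleMask(samples[[i]])
      m[, seq_len(ncol(m) / 2)] <- 0   # drop half the prediction
      m * 0.9 + 0.05
    })
  ev <- evaluateModel(half, samples)
  expect_equal(unname(ev@summary["dice"]), mean(ev@perImage$dice))
  expect_equal(unname(ev@summary["iou"]), mean(ev@perImage$iou))
  expect_equal(unname(ev@summary["accuracy"]), mean(ev@perImage$accuracy))
})

test_that("reportResults orders columns Dice, Accuracy, IoU and marks ties", {
  mk <- function(name, d, a, j)
    new("EvaluationResult", perImage = data.frame(),
        summary = c(dice = d, iou = j, accuracy = a), modelName = name)
  out <- capture.output(
    df <- reportResults(list(mk("m1", 0.9, 0.95, 0.85),
                             mk("m2", 0.9, 0.93, 0.88))))
  expect_equal(colnames(df), c("Model", "Dice", "Accuracy", "IoU"))
  best <- attr(df, "best")
  expect_true(all(best[, "Dice"]))            # tie: both marked
  expect_equal(best[, "Accuracy"], c(TRUE, FALSE))
  expect_equal(best[, "IoU"], c(FALSE, TRUE))
  single <- capture.output(dfs <- reportResults(mk("only", 0.5, 0.5, 0.5)))
  expect_true(all(attr(dfs, "best")))
})

test_that("history files round-trip", {
  h <- data.frame(epoch = 1:3, train_loss = c(0.5, 0.4, 0.3),
                  val_loss = c(0.6, 0.5, 0.45), val_dice = c(0.5, 0.6, 0.7),
                  val_iou = c(0.4, 0.5, 0.6),
                  val_accuracy = c(0.8, 0.85, 0.9))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeHistory(h, p)
  h2 <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(h2, h)
})

test_that("deep supervision trains on the mean loss over all heads", {
  spec <- modelSpec("unetpp_improved", "plain", baseWidth = 4L,
                    decoderWidths = c(4, 8, 8, 8, 8), dropoutRate = 0,
                    batchNorm = FALSE, deepSupervision = TRUE)
  m <- buildModel(spec, initSeed = 6)
  s <- quickTrainData(n = 1L, seed = 12L)[[1]]
  x <- dermaseg:::networkInput(grayWorldNormalize(sampleImage(s)))
  y <- sampleMask(s)
  b <- dermaseg:::imagesToBatch(list(x))
  yv <- dermaseg:::masksToBatch(list(y))
  # without batch norm or dropout, train- and eval-mode forwards agree, so
  # the per-head losses can be recomputed from eval-mode logits
  zs <- dermaseg:::eng_node_outputs(m@ptr, b$x, as.integer(b$dims),
                                    as.integer(m@outputNodes - 1L))
  alpha <- 0.5
  perHead <- vapply(zs, function(z) {
    p <- 1 / (1 + exp(-as.numeric(z)))
    combinedLoss(p, yv, alpha)
  }, numeric(1))
  got <- dermaseg:::eng_train_step(m@ptr, b$x, as.integer(b$dims), yv,
                                   alpha, 0, 0.9, 0.999, 1e-8)
  expect_length(perHead, 4L)
  expect_equal(got$loss, mean(perHead), tolerance = 1e-5)
})
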