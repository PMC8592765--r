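# Loss closed forms, binarisation, confusion counts and metric identities.

test_that("BCE matches its closed forms", {
  y <- matrix(c(0, 1), 8, 8)
  expect_lt(bceLoss(y, y), 1e-6)                       # perfect prediction
  expect_equal(bceLoss(matrix(0.5, 8, 8), y), log(2), tolerance = 1e-12)
  expect_equal(bceLoss(1 - y, y), -log(1e-7), tolerance = 1e-6)  # clamp max
  expect_error(bceLoss(matrix(0.5, 4, 4), matrix(1, 4, 5)),
               class = "dermaseg_validation_error")
})

test_that("soft Dice loss hits its closed forms", {
  y <- matrix(0, 10, 10); y[1:5, ] <- 1
  expect_lt(diceLoss(y, y), 1e-6)
  disj <- matrix(0, 10, 10); disj[6:10, ] <- 1
  expect_equal(diceLoss(disj, y), 1, tolerance = 1e-5)
  # p = 0.5 everywhere, y half ones: 1 - (N/2)/N = 0.5
  expect_equal(diceLoss(matrix(0.5, 10, 10), y), 0.5, tolerance = 1e-6)
})

test_that("combined loss is the alpha-weighted mixture", {
  set.seed(4)
  p <- matrix(runif(64), 8, 8)
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_identical(combinedLoss(p, y, 0), bceLoss(p, y))
  expect_identical(combinedLoss(p, y, 1), diceLoss(p, y))
  yh <- matrix(0, 10, 10); yh[1:5, ] <- 1
  expect_equal(combinedLoss(matrix(0.5, 10, 10), yh, 0.5),
               0.5 * log(2) + 0.5 * 0.5, tolerance = 1e-6)
  expect_equal(0.5 * log(2) + 0.25, 0.596574, tolerance = 1e-6)
  expect_error(combinedLoss(p, y, 1.5), class = "dermaseg_config_error")
})

test_that("combined loss is bounded by its two components", {
  set.seed(11)
  for (i in 1:200) {
    p <- matrix(runif(36, 0.01, 0.99), 6, 6)
    y <- matrix(rbinom(36, 1, runif(1, 0.1, 0.9)), 6, 6)
    a <- runif(1)
    b <- bceLoss(p, y); d <- diceLoss(p, y)
    l <- combinedLoss(p, y, a)
    expect_gte(l, min(b, d) - 1e-12)
    expect_lte(l, max(b, d) + 1e-12)
  }
})

test_that("binarize uses strict inequality with ties to background", {
  expect_equal(binarize(c(0.4, 0.5, 0.6)), c(0, 0, 1))
  expect_equal(binarize(matrix(0.2, 2, 2), 0), matrix(1, 2, 2))
  p <- matrix(runif(16), 4, 4)
  b1 <- binarize(p, 0.3)
  expect_identical(binarize(b1, 0.3), b1)  # idempotent on binary output
})

test_that("confusion counts enumerate the four cells", {
  pred <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  truth <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  cc <- confusionCounts(pred, truth)
  expect_equal(unname(counts(cc)), c(1, 1, 1, 1))
  same <- confusionCounts(truth, truth)
  expect_equal(same@fp + same@fn, 0)
  expect_equal(sum(counts(cc)), 4)
  expect_error(confusionCounts(matrix(0.5, 2, 2), truth),
               class = "dermaseg_validation_error")
})

test_that("metric formulas match hand-computed values", {
  cc <- new("ConfusionCounts", tp = 3, fp = 1, fn = 2, tn = 4)
  expect_equal(diceScore(cc), 6 / 9)
  expect_equal(iouScore(cc), 3 / 6)
  expect_equal(accuracyScore(new("ConfusionCounts", tp = 1, fp = 1,
                                 fn = 1, tn = 1)), 0.5)
  empty <- new("ConfusionCounts", tp = 0, fp = 0, fn = 0, tn = 5)
  expect_error(diceScore(empty), class = "dermaseg_undefined_metric_error")
  expect_error(iouScore(empty), class = "dermaseg_undefined_metric_error")
  expect_error(accuracyScore(new("ConfusionCounts", tp = 0, fp = 0, fn = 0,
                                 tn = 0)),
               class = "dermaseg_undefined_metric_error")
})

test_that("metrics agree with brute-force pixel enumeration", {
  # random binary mask pairs; oracle = direct pixel counting loops
  set.seed(21)
  for (i in 1:50) {
    pred <- matrix(rbinom(9, 1, 0.5), 3, 3)
    truth <- matrix(rbinom(9, 1, 0.5), 3, 3)
    tp <- fp <- fn <- tn <- 0
    for (r in 1:3) for (c in 1:3) {
      if (pred[r, c] == 1 && truth[r, c] == 1) tp <- tp + 1
      if (pred[r, c] == 1 && truth[r, c] == 0) fp <- fp + 1
      if (pred[r, c] == 0 && truth[r, c] == 1) fn <- fn + 1
      if (pred[r, c] == 0 && truth[r, c] == 0) tn <- tn + 1
    }
    cc <- confusionCounts(pred, truth)
    expect_equal(unname(counts(cc)), c(tp, fp, fn, tn))
    if (tp + fp + fn > 0) {
      expect_equal(diceScore(cc), 2 * tp / (2 * tp + fp + fn))
      expect_equal(iouScore(cc), tp / (tp + fp + fn))
    }
    expect_equal(accuracyScore(cc), (tp + tn) / 9)
  }
})

test_that("Dice and IoU obey dice = 2 iou / (1 + iou)", {
  set.seed(33)
  for (i in 1:500) {
    cc <- new("ConfusionCounts", tp = rpois(1, 20), fp = rpois(1, 10),
              fn = rpois(1, 10), tn = rpois(1, 50))
    if (cc@tp + cc@fp + cc@fn == 0) next
    d <- diceScore(cc); j <- iouScore(cc)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_gte(d, j)
  }
})

test_that("soft Dice approaches 1 - hard Dice in the binary limit", {
  set.seed(5)
  for (i in 1:20) {
    pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
    truth <- matrix(rbinom(64, 1, 0.4), 8, 8)
    if (sum(pred) + sum(truth) == 0) next
    cc <- confusionCounts(pred, truth)
    expect_equal(diceLoss(pred, truth), 1 - diceScore(cc), tolerance = 1e-4)
  }
})
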