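# Readers, binarisation, splits and manifests.

test_that("ISIC pair reading binarises masks with the >127 rule", {
  d <- withr::local_tempdir()
  s <- toySample()
  ip <- file.path(d, "ISIC_0001.png")
  mp <- file.path(d, "ISIC_0001_segmentation.png")
  dermaseg:::writeRaster(sampleImage(s), ip)
  # mask with an anti-aliased boundary value 128 (-> 1) and 127 (-> 0)
  m255 <- sampleMask(s) * 255
  m255[1, 1] <- 128
  m255[1, 2] <- 127
  dermaseg:::writeRaster(m255, mp)
  r <- readIsicPair(ip, mp)
  expect_s4_class(r, "DermoscopySample")
  expect_identical(sampleSource(r), "isic")
  expect_identical(sampleId(r), "ISIC_0001")
  expect_equal(sampleMask(r)[1, 1], 1)
  expect_equal(sampleMask(r)[1, 2], 0)
  expect_true(all(sampleMask(r) %in% c(0, 1)))
  # foreground set preserved where the mask was already binary
  expect_equal(sampleMask(r)[-1, ], sampleMask(s)[-1, ])
})

test_that("shape mismatch and missing files raise classed errors", {
  d <- withr::local_tempdir()
  s <- toySample()
  ip <- file.path(d, "a.png")
  mp <- file.path(d, "a_segmentation.png")
  dermaseg:::writeRaster(sampleImage(s), ip)
  dermaseg:::writeRaster(matrix(255, 32, 48), mp)
  err <- expect_error(readIsicPair(ip, mp), class = "dermaseg_validation_error")
  expect_match(conditionMessage(err), "64x64")
  expect_match(conditionMessage(err), "32x48")
  expect_error(readIsicPair(file.path(d, "nope.png"), mp),
               class = "dermaseg_input_error")
})

test_that("PH2 cases round-trip (BMP), with ambiguity and channel collapse", {
  d <- withr::local_tempdir()
  cfg <- syntheticConfig(nSamples = 2L, seed = 42L)
  generateDataset(cfg, layout = "ph2", outDir = d, overwrite = TRUE)
  caseDir <- file.path(d, "SYN_0001")
  r <- readPh2Case(caseDir)
  expect_identical(sampleSource(r), "ph2")
  expect_identical(sampleId(r), "SYN_0001")
  orig <- generateSample(cfg, 1L)
  expect_equal(sampleMask(r), sampleMask(orig), ignore_attr = TRUE)
  expect_equal(sampleImage(r), sampleImage(orig))

  expect_error(readPh2Case(withr::local_tempdir()),
               class = "dermaseg_ambiguity_error")

  # 3-channel mask with identical channels collapses to one
  d2 <- withr::local_tempdir()
  dir.create(file.path(d2, "case1"))
  dermaseg:::writeRaster(sampleImage(orig), file.path(d2, "case1", "case1.bmp"))
  m3 <- array(rep(sampleMask(orig) * 255, 3L),
              c(dim(sampleMask(orig)), 3L))
  dermaseg:::writeRaster(m3, file.path(d2, "case1", "case1_lesion.bmp"))
  r3 <- readPh2Case(file.path(d2, "case1"))
  expect_equal(r3@mask, orig@mask, ignore_attr = TRUE)
})

test_that("BMP codec round-trips 24-bit colour and 8-bit grey exactly", {
  d <- withr::local_tempdir()
  set.seed(1)
  img <- array(sample(0:255, 31 * 45 * 3, replace = TRUE), c(31, 45, 3))
  p <- file.path(d, "x.bmp")
  dermaseg:::writeBMP(img, p)
  expect_identical(dermaseg:::readBMP(p), img + 0.0)
  g <- matrix(sample(0:255, 33 * 31, replace = TRUE), 33, 31)
  dermaseg:::writeBMP(g, p)
  expect_identical(dermaseg:::readBMP(p), g + 0.0)
})

test_that("splitDataset sizes follow the rounding rule, remainder to train", {
  ids <- sprintf("s%03d", 1:200)
  sp <- splitDataset(ids, c(0.8, 0, 0.2), seed = 1)
  expect_length(sp@train, 160L)
  expect_length(sp@validation, 0L)
  expect_length(sp@test, 40L)

  sp2 <- splitDataset(sprintf("t%02d", 1:10), c(0.5, 0.2, 0.3), seed = 7)
  expect_equal(lengths(list(sp2@train, sp2@validation, sp2@test)),
               c(5L, 2L, 3L))
  all_ids <- c(sp2@train, sp2@validation, sp2@test)
  expect_setequal(all_ids, sprintf("t%02d", 1:10))
  expect_false(anyDuplicated(all_ids) > 0)

  expect_identical(splitDataset(ids, c(0.8, 0, 0.2), seed = 5),
                   splitDataset(ids, c(0.8, 0, 0.2), seed = 5))
  expect_error(splitDataset(c("a", "b"), c(0.5, 0.25, 0.25), 1),
               class = "dermaseg_size_error")
  expect_error(splitDataset(ids, c(0.5, 0.2, 0.2), 1),
               class = "dermaseg_config_error")
})

test_that("kfoldSplit partitions ids with balanced folds", {
  ids <- sprintf("s%02d", 1:10)
  folds <- kfoldSplit(ids, k = 5, seed = 2)
  expect_length(folds, 5L)
  vals <- lapply(folds, `[[`, "validation")
  expect_true(all(lengths(vals) == 2L))
  expect_setequal(unlist(vals), ids)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    expect_setequal(c(f$train, f$validation), ids)
  }
  sizes <- sort(lengths(lapply(kfoldSplit(sprintf("u%d", 1:7), 5, 3),
                               `[[`, "validation")), decreasing = TRUE)
  expect_equal(sizes, c(2L, 2L, 1L, 1L, 1L))
  expect_error(kfoldSplit(ids, k = 11, seed = 1),
               class = "dermaseg_size_error")
})

test_that("split manifests round-trip through disk", {
  sp <- splitDataset(sprintf("s%03d", 1:50), c(0.6, 0.2, 0.2), seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeSplitManifest(sp, p)
  sp2 <- readSplitManifest(p)
  expect_setequal(sp2@train, sp@train)
  expect_setequal(sp2@validation, sp@validation)
  expect_setequal(sp2@test, sp@test)
})

test_that("DermoscopySample validity enforces its invariants", {
  s <- toySample()
  expect_error(dermoscopySample("x", sampleImage(s), sampleMask(s)[1:32, ]),
               "differ")
  badMask <- sampleMask(s)
  badMask[1, 1] <- 0.5
  expect_error(dermoscopySample("x", sampleImage(s), badMask), "exactly 0 or 1")
  expect_error(dermoscopySample("x", array(0, c(16, 16, 3)),
                                matrix(0, 16, 16)), "at least 32")
})
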