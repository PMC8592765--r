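# Synthetic dermoscopy generator.

test_that("samples are bit-identical for a fixed seed and differ across seeds", {
  cfg <- syntheticConfig(seed = 7)
  s1 <- generateSample(cfg, 3L)
  s2 <- generateSample(cfg, 3L)
  expect_identical(sampleImage(s1), sampleImage(s2))
  expect_identical(sampleMask(s1), sampleMask(s2))

  cfgB <- syntheticConfig(seed = 8)
  masksA <- lapply(1:6, function(i) sampleMask(generateSample(cfg, i)))
  masksB <- lapply(1:6, function(i) sampleMask(generateSample(cfgB, i)))
  for (a in masksA) for (b in masksB) expect_false(identical(a, b))
})

test_that("zero irregularity yields an ellipse with the closed-form area", {
  cfg <- syntheticConfig(boundaryIrregularity = 0, hairProbability = 0,
                         lesionAreaRange = c(0.05, 0.2), seed = 13)
  for (i in 1:8) {
    s <- generateSample(cfg, i)
    geo <- attr(s@mask, "geometry")
    measured <- sum(sampleMask(s))
    expect_lt(abs(measured - pi * geo$a * geo$b) / (pi * geo$a * geo$b),
              0.02)
  }
})

test_that("the lesion interior is darker than the background", {
  cfg <- syntheticConfig(lesionContrast = 0.5, seed = 21)
  for (i in 1:5) {
    s <- generateSample(cfg, i)
    m <- sampleMask(s)
    inside <- mean(sampleImage(s)[m == 1])
    outside <- mean(sampleImage(s)[m == 0])
    expect_lt(inside, outside - 20)
  }
})

test_that("mask area fractions always fall inside the configured range", {
  cfg <- syntheticConfig(seed = 5)
  fr <- vapply(1:100, function(i) mean(sampleMask(generateSample(cfg, i))),
               numeric(1))
  expect_true(all(fr >= cfg@lesionAreaRange[1]))
  expect_true(all(fr <= cfg@lesionAreaRange[2]))
})

test_that("every generated sample satisfies the sample invariants", {
  cfg <- syntheticConfig(seed = 9, hairProbability = 1)
  for (i in 1:10) {
    s <- generateSample(cfg, i)
    expect_true(validObject(s))
    expect_equal(dim(sampleImage(s))[1:2], dim(sampleMask(s)))
    expect_true(all(sampleMask(s) %in% c(0, 1)))
    expect_true(all(sampleImage(s) >= 0 & sampleImage(s) <= 255))
  }
})

test_that("dataset writing follows the layouts and round-trips", {
  cfg <- syntheticConfig(nSamples = 4L, seed = 17)
  dIsic <- withr::local_tempdir()
  man <- generateDataset(cfg, layout = "isic", outDir = dIsic,
                         overwrite = TRUE)
  expect_equal(nrow(man), 4L)
  expect_length(list.files(dIsic, pattern = "_segmentation\\.png$"), 4L)
  expect_length(list.files(dIsic, pattern = "^SYN_\\d+\\.png$"), 4L)
  back <- readDataset(dIsic, "isic")
  ids <- vapply(back, sampleId, character(1))
  for (i in 1:4) {
    orig <- generateSample(cfg, i)
    got <- back[[which(ids == sampleId(orig))]]
    expect_identical(unname(sampleMask(got)),
                     unname(`attributes<-`(sampleMask(orig),
                                           list(dim = dim(sampleMask(orig))))))
    expect_equal(sampleImage(got), sampleImage(orig))
  }

  dPh2 <- withr::local_tempdir()
  generateDataset(cfg, layout = "ph2", outDir = dPh2, overwrite = TRUE)
  cases <- list.dirs(dPh2, recursive = FALSE)
  expect_length(cases, 4L)
  for (cs in cases) {
    fl <- list.files(cs)
    expect_length(fl, 2L)
    expect_length(grep("_lesion\\.bmp$", fl), 1L)
  }

  # refusal on non-empty target
  expect_error(generateDataset(cfg, layout = "isic", outDir = dIsic),
               class = "dermaseg_input_error")
})

test_that("config invariants are validated", {
  expect_error(syntheticConfig(lesionAreaRange = c(0.5, 0.2)), "lo < hi")
  expect_error(syntheticConfig(hairProbability = 1.5), "0, 1")
  expect_error(syntheticConfig(size = c(60, 60)), "32")
})
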