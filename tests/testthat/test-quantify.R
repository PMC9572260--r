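test_that("manualRate follows the mass formula and validates inputs", {
  expect_equal(manualRate(0, 500), 0)
  expect_equal(manualRate(5, 500), 1)       # 5 g impurity in a 500 g sample
  expect_equal(manualRate(500, 500), 100)
  expect_error(manualRate(1, 0), "> 0")
  expect_error(manualRate(6, 5), "exceeds")
})

test_that("pixelRate follows the quantification model", {
  expect_equal(pixelRate(c(Tw = 5000L, Tz = 0L), 11.8906), 0)
  expect_equal(pixelRate(c(Tw = 777L, Tz = 777L), 1), 50)
  expect_equal(pixelRate(c(Tw = 10000L, Tz = 1000L), 11.8906),
               1000 / (1000 + 11.8906 * 10000) * 100, tolerance = 1e-12)
  expect_warning(u <- pixelRate(c(Tw = 0L, Tz = 0L), 2), "undefined")
  expect_true(isUndefined(u))
  expect_error(pixelRate(c(Tw = 1L, Tz = 1L), 0), "> 0")
})

test_that("pixelRate is bounded and strictly monotone in its arguments", {
  set.seed(12)
  for (i in 1:25) {
    tw <- sample(1:5000, 1); tz <- sample(1:5000, 1)
    d <- runif(1, 0.5, 20)
    r <- pixelRate(c(Tw = tw, Tz = tz), d)
    expect_gte(r, 0); expect_lte(r, 100)
    expect_gt(pixelRate(c(Tw = tw, Tz = tz + 50L), d), r)
    expect_lt(pixelRate(c(Tw = tw + 50L, Tz = tz), d), r)
    expect_lt(pixelRate(c(Tw = tw, Tz = tz), d + 1), r)
  }
})

test_that("calibrateDelta recovers the density ratio", {
  one <- list(list(counts = c(Tw = 1000L, Tz = 1000L), w = 3, wz = 1))
  expect_equal(calibrateDelta(one)$delta, 2)

  equal <- list(list(counts = c(Tw = 2000L, Tz = 500L), w = 2.5, wz = 0.5))
  expect_equal(calibrateDelta(equal)$delta, 1)

  # noiseless synthetic samples at the laboratory ratio recover it exactly
  mm <- MassModel(grainMassPerKpx = 2.14,
                  impurityMassPerKpx = 2.14 / 11.8906, noiseCv = 0)
  samples <- lapply(1:6, function(i) {
    s <- renderScene(SceneSpec(64, 64, nGrains = 25, nImpurities = 3,
                               grainAxisRange = c(2.5, 5),
                               impurityLengthRange = c(10, 24),
                               impurityWidthRange = c(2, 4), seed = i))
    ws <- sampleMasses(trueCounts(s), mm, seed = i)
    list(counts = trueCounts(s), w = ws[["w"]], wz = ws[["wz"]])
  })
  cal <- calibrateDelta(samples)
  expect_equal(cal$delta, 11.8906, tolerance = 1e-10)
  expect_equal(cal$nSamples, 6L)
  expect_equal(unname(cal$dispersion), c(0, 0), tolerance = 1e-10)

  mor <- calibrateDelta(samples, method = "mean-of-ratios")
  expect_equal(mor$delta, 11.8906, tolerance = 1e-10)
})

test_that("calibration rejects unusable sample sets", {
  noImp <- list(list(counts = c(Tw = 1000L, Tz = 0L), w = 2, wz = 0))
  expect_error(calibrateDelta(noImp), "impurity component")
  noGrain <- list(list(counts = c(Tw = 0L, Tz = 1000L), w = 1, wz = 1))
  expect_error(calibrateDelta(noGrain), "grain component")
  expect_error(calibrateDelta(list()), "no calibration samples")
  bad <- list(list(counts = c(Tw = 10L, Tz = 10L), w = 1, wz = 2))
  expect_error(calibrateDelta(bad), "wz <= w")
})

test_that("calibration files round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  cal <- calibrateDelta(list(list(counts = c(Tw = 1000L, Tz = 1000L),
                                  w = 3, wz = 1)))
  writeCalibration(cal, f, note = "unit test")
  back <- readCalibration(f)
  expect_equal(back$delta, 2)
  expect_equal(back$note, "unit test")
  expect_error(readCalibration(file.path(tempdir(), "none.json")), "not found")
})

test_that("detectImpurity ties segmentation to the quantification model", {
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                              inputSize = c(64, 64)), seed = 6)
  img <- imageOf(overfitScene(3))
  r1 <- detectImpurity(img, m, delta = 11.8906, imageId = "s3")
  mask <- predictMask(m, img)
  expect_equal(r1$Tw, sum(mask == 1L))
  expect_equal(r1$Tz, sum(mask == 2L))
  if (!isUndefined(r1$Pz))
    expect_equal(r1$Pz, pixelRate(c(Tw = r1$Tw, Tz = r1$Tz), 11.8906))
  r2 <- detectImpurity(img, m, delta = 11.8906, imageId = "s3")
  expect_identical(r1[setdiff(names(r1), "timestamp")],
                   r2[setdiff(names(r2), "timestamp")])
})

test_that("an all-background prediction logs an undefined detection", {
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                              inputSize = c(64, 64)), seed = 6)
  # force the classifier to always pick background via its bias
  params <- m@graph$params
  cls <- params[[length(params) - 1L]]   # classifier conv weight
  bias <- params[[length(params)]]       # classifier conv bias
  cls$w[] <- 0
  bias$w <- c(100, 0, 0)
  img <- imageOf(overfitScene(5))
  expect_warning(r <- detectImpurity(img, m, 11.8906), "all-background")
  expect_true(isUndefined(r$Pz))
  expect_equal(r$Tw + r$Tz, 0)

  f <- withr::local_tempfile(fileext = ".csv")
  df <- writeDetectionLog(list(r), f)
  expect_true(is.na(df$Pz[1]))
  expect_true(file.exists(f))
})

test_that("delta recovery stays within 5% under 5% mass noise", {
  # 30 paired samples per replicate, multiplicative CV 5%; pixel counts from
  # rendered scenes, reused across replicates with fresh weighing noise
  mm <- MassModel(grainMassPerKpx = 2.14,
                  impurityMassPerKpx = 2.14 / 11.8906, noiseCv = 0.05)
  counts <- lapply(1:30, function(i)
    trueCounts(renderScene(SceneSpec(48, 48, nGrains = 15, nImpurities = 2,
                                     grainAxisRange = c(2, 4.5),
                                     impurityLengthRange = c(8, 20),
                                     impurityWidthRange = c(2, 4), seed = i))))
  hits <- vapply(1:30, function(rep) {
    samples <- lapply(seq_along(counts), function(i) {
      ws <- sampleMasses(counts[[i]], mm, seed = rep * 1000L + i)
      list(counts = counts[[i]], w = ws[["w"]], wz = ws[["wz"]])
    })
    abs(calibrateDelta(samples)$delta / 11.8906 - 1) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
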