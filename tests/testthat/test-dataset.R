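test_that("resizePair resamples images bilinearly and masks with nearest-neighbour", {
  s <- renderScene(SceneSpec(40, 32, nGrains = 8, nImpurities = 1, seed = 2))
  # SceneSpec(width=40, height=32) renders a 32 x 40 array
  same <- resizePair(imageOf(s), maskOf(s), 32, 40)
  expect_identical(same$image, imageOf(s))
  expect_identical(same$mask, maskOf(s))

  small <- resizePair(imageOf(s), maskOf(s), 16, 16)
  expect_equal(dim(small$image), c(16, 16, 3))
  expect_equal(dim(small$mask), c(16, 16))
  expect_true(all(small$mask %in% 0:2))

  flat <- array(0.42, dim = c(20, 20, 3))
  out <- resizePair(flat, NULL, 48, 48)$image
  expect_equal(range(out), c(0.42, 0.42), tolerance = 1e-12)

  expect_error(resizePair(flat, NULL, 0, 16), "positive|whole|>=")
})

test_that("augmentPair produces the six protocol variants", {
  s <- renderScene(SceneSpec(32, 32, nGrains = 10, nImpurities = 2, seed = 5))
  img <- imageOf(s); msk <- maskOf(s)
  v <- augmentPair(img, msk)
  expect_named(v, c("rot90", "rot270", "scale0.6", "scale1.8", "mirrorH", "mirrorV"))

  # rotations and mirrors permute pixels: per-class counts unchanged
  for (nm in c("rot90", "rot270", "mirrorH", "mirrorV")) {
    expect_equal(sum(v[[nm]]$mask == 1L), sum(msk == 1L), info = nm)
    expect_equal(sum(v[[nm]]$mask == 2L), sum(msk == 2L), info = nm)
  }
  # scaling restores the canvas and keeps a valid label set
  for (nm in c("scale0.6", "scale1.8")) {
    expect_equal(dim(v[[nm]]$mask), dim(msk), info = nm)
    expect_equal(dim(v[[nm]]$image), dim(img), info = nm)
    expect_true(all(v[[nm]]$mask %in% 0:2), info = nm)
  }
  # 0.6x zoom-out pads the border with background
  expect_true(all(v$`scale0.6`$mask[1:2, ] == 0L))
  expect_true(all(v$`scale0.6`$mask[, 31:32] == 0L))
})

test_that("four 90-degree rotations restore the original pair", {
  s <- renderScene(SceneSpec(32, 24, nGrains = 6, nImpurities = 1, seed = 9))
  img <- imageOf(s); msk <- maskOf(s)
  for (k in 1:4) {
    v <- augmentPair(img, msk)$rot90
    img <- v$image; msk <- v$mask
  }
  expect_identical(img, imageOf(s))
  expect_identical(msk, maskOf(s))
})

test_that("augmentation multiplies the set size by exactly 7", {
  pairs <- lapply(1:12, function(i)
    scenePair(SceneSpec(16, 16, nGrains = 3, nImpurities = 1,
                        grainAxisRange = c(1.5, 3),
                        impurityLengthRange = c(4, 8),
                        impurityWidthRange = c(1.5, 3), seed = i)))
  aug <- augmentSet(pairs)
  expect_length(aug, 84L)
  # originals are retained in slot 1 of each block of 7
  expect_identical(aug[[1]]$mask, pairs[[1]]$mask)
  expect_identical(aug[[8]]$mask, pairs[[2]]$mask)
})

test_that("splitDataset is disjoint, exhaustive for the requested counts, and seeded", {
  files <- sprintf("img%03d.png", 1:50)
  sp <- splitDataset(files, c(35, 5, 10), seed = 3)
  expect_length(sp$train, 35L); expect_length(sp$val, 5L); expect_length(sp$test, 10L)
  all3 <- c(sp$train, sp$val, sp$test)
  expect_equal(anyDuplicated(all3), 0L)
  expect_setequal(all3, files)

  expect_identical(splitDataset(files, c(35, 5, 10), seed = 3), sp)
  expect_false(identical(splitDataset(files, c(35, 5, 10), seed = 4)$train, sp$train))

  allTrain <- splitDataset(files, c(50, 0, 0), seed = 1)
  expect_length(allTrain$train, 50L); expect_length(allTrain$test, 0L)

  expect_error(splitDataset(files, c(45, 5, 10), seed = 1), "at least 60")
})

test_that("loadDataset returns pairs matching the manifest, optionally resized", {
  dir <- withr::local_tempdir()
  man <- makeDataset(SceneSpec(48, 48, nGrains = 10, nImpurities = 2, seed = 4),
                     3, dir, seed = 11)
  pairs <- loadDataset(dir)
  expect_length(pairs, 3L)
  expect_equal(sum(pairs[[2]]$mask == 1L), man$Tw[2])

  sub <- loadDataset(dir, images = man$image[2], height = 32, width = 32)
  expect_length(sub, 1L)
  expect_equal(dim(sub[[1]]$image), c(32, 32, 3))
  expect_error(loadDataset(withr::local_tempdir()), "manifest")
})
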