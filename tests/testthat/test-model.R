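test_that("every backbone honours the shape contract at desk scale", {
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  for (bb in c("tiny", "mobilenetv2", "resnet50", "xception65")) {
    m <- buildModel(ModelConfig(bb, widthMultiplier = 0.05,
                                inputSize = c(32, 32)), seed = 1)
    mask <- predictMask(m, img)
    expect_equal(dim(mask), c(32, 32), info = bb)
    expect_true(all(mask %in% 0:2), info = bb)
  }
  # output stride 8 variant
  m8 <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                               outputStride = 8L, inputSize = c(32, 32)), seed = 1)
  expect_equal(dim(predictMask(m8, img)), c(32, 32))
})

test_that("construction and inference are deterministic under a seed", {
  cfg <- ModelConfig("tiny", widthMultiplier = 0.25, inputSize = c(64, 64))
  m1 <- buildModel(cfg, seed = 7); m2 <- buildModel(cfg, seed = 7)
  w1 <- lapply(m1@graph$params, function(p) p$w)
  w2 <- lapply(m2@graph$params, function(p) p$w)
  expect_identical(w1, w2)
  m3 <- buildModel(cfg, seed = 8)
  expect_false(identical(w1, lapply(m3@graph$params, function(p) p$w)))

  img <- imageOf(overfitScene(1))
  expect_identical(predictMask(m1, img), predictMask(m1, img))
})

test_that("configuration errors are caught by name", {
  expect_error(buildModel(ModelConfig("vgg16")), "unknown backbone")
  expect_error(ModelConfig("tiny", widthMultiplier = 0), "widthMultiplier")
  expect_error(ModelConfig("tiny", inputSize = c(100, 100)), "16")
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                              inputSize = c(64, 64)), seed = 1)
  expect_error(predictMask(m, array(0, dim = c(32, 32, 3))), "64 x 64")
})

test_that("a tiny forward pass at 64x64 runs in under a second", {
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                              inputSize = c(64, 64)), seed = 1)
  img <- imageOf(overfitScene(2))
  predictMask(m, img)  # warm the geometry caches
  elapsed <- system.time(predictMask(m, img))["elapsed"]
  expect_lt(unname(elapsed), 1)
})

test_that("training edge cases behave as specified", {
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                              inputSize = c(64, 64)), seed = 1)
  w0 <- lapply(m@graph$params, function(p) p$w)
  pairs <- lapply(1:2, function(i) {
    s <- overfitScene(i); list(image = imageOf(s), mask = maskOf(s))
  })
  m0 <- trainModel(m, pairs, NULL, TrainConfig(epochs = 0L, seed = 1))
  expect_identical(lapply(m0@graph$params, function(p) p$w), w0)
  expect_error(trainModel(m, list(), NULL, TrainConfig(epochs = 1L)),
               "empty training set")
  expect_error(TrainConfig(device = "gpu"), "cpu")
})

test_that("training is reproducible and the history is recorded", {
  pairs <- lapply(1:2, function(i) {
    s <- overfitScene(i); list(image = imageOf(s), mask = maskOf(s))
  })
  tc <- TrainConfig(epochs = 2L, batchSize = 1L, learningRate = 1e-3, seed = 5)
  run <- function() {
    m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                                inputSize = c(64, 64)), seed = 3)
    trainModel(m, pairs, NULL, tc)
  }
  h1 <- trainHistory(run()); h2 <- trainHistory(run())
  expect_identical(h1$loss, h2$loss)
  expect_equal(h1$epoch, 1:2)
  expect_true(all(diff(h1$loss) < 0))
})

test_that("an overfit run memorises five scenes to high pixel accuracy", {
  pairs <- lapply(1:5, function(i) {
    s <- overfitScene(i); list(image = imageOf(s), mask = maskOf(s))
  })
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.5,
                              inputSize = c(64, 64)), seed = 1)
  m <- suppressWarnings(trainModel(
    m, pairs, NULL,
    TrainConfig(epochs = 90L, batchSize = 1L, learningRate = 5e-3,
                lrDecayFactor = 0.5, lrDecayEvery = 30L, seed = 2)))
  acc <- mean(vapply(pairs, function(p)
    mean(predictMask(m, p$image) == p$mask), numeric(1)))
  expect_gte(acc, 0.95)
})

test_that("checkpoints restore config, weights and history faithfully", {
  f <- withr::local_tempfile(fileext = ".rds")
  pairs <- list({ s <- overfitScene(4); list(image = imageOf(s), mask = maskOf(s)) })
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                              inputSize = c(64, 64)), seed = 2)
  m <- trainModel(m, pairs, NULL,
                  TrainConfig(epochs = 1L, batchSize = 1L, seed = 3))
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(predictMask(m2, pairs[[1]]$image),
                   predictMask(m, pairs[[1]]$image))
  expect_equal(trainHistory(m2), trainHistory(m))
  expect_equal(modelConfig(m2)@backbone, "tiny")
})

test_that("measureSpeed reports a positive finite mean per image", {
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                              inputSize = c(64, 64)), seed = 1)
  imgs <- list(imageOf(overfitScene(1)), imageOf(overfitScene(2)))
  ms <- measureSpeed(m, imgs)
  expect_true(is.finite(ms) && ms > 0)
  expect_match(attr(ms, "hardware"), "CPU")
})
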