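test_that("confusion counts match hand counts on a toy mask", {
  # 4x4 toy: truth has 6 grain pixels; prediction marks 5 of them plus 2
  # background pixels as grain
  truth <- matrix(0L, 4, 4); truth[1:6] <- 1L
  pred <- truth
  pred[6] <- 0L          # one grain pixel missed
  pred[c(7, 8)] <- 1L    # two background pixels called grain
  tab <- confusionTable(pred, truth, 1L)
  expect_equal(tab[c("TP", "FP", "FN")], list(TP = 5L, FP = 2L, FN = 1L))

  perfect <- confusionTable(truth, truth, 1L)
  expect_equal(perfect$FP, 0L); expect_equal(perfect$FN, 0L)
  expect_equal(perfect$TP, 6L)

  none <- confusionTable(matrix(0L, 4, 4), truth, 1L)
  expect_equal(none[c("TP", "FP", "FN")], list(TP = 0L, FP = 0L, FN = 6L))

  expect_error(confusionTable(matrix(0L, 2, 2), truth, 1L), "differ")
})

test_that("metric formulas reproduce the toy-table arithmetic", {
  tab <- list(classId = 1L, TP = 5L, FP = 2L, FN = 1L)
  P <- pixelPrecision(tab); R <- pixelRecall(tab)
  expect_equal(round(P, 4), 0.7143)
  expect_equal(round(R, 4), 0.8333)
  expect_equal(round(f1Score(P, R), 4), 0.7692)
  expect_equal(round(iouScore(tab), 4), 0.6250)
  # harmonic-mean fixed point
  expect_equal(f1Score(0.63, 0.63), 0.63)
  # identity route agrees with the count route
  expect_equal(unname(metricsFromPR(P, R)["FIOU"]), iouScore(tab))
})

test_that("zero denominators yield explicit undefined markers", {
  empty <- list(classId = 2L, TP = 0L, FP = 0L, FN = 0L)
  expect_warning(p <- pixelPrecision(empty), "undefined")
  expect_true(isUndefined(p))
  expect_warning(r <- pixelRecall(empty), "undefined")
  expect_true(isUndefined(r))
  expect_warning(m <- metricsFromPR(0, 0.5), "undefined")
  expect_true(all(isUndefined(m)))
  expect_true(isUndefined(f1Score(NA_real_, 0.5)))
})

test_that("meanIoU averages defined values and rejects empty input", {
  expect_equal(meanIoU(c(0.5, 0.5)), 0.5)
  expect_equal(meanIoU(c(0.7186, 0.7727)), 0.74565)
  expect_warning(m <- meanIoU(c(0.6, NA)), "dropping")
  expect_equal(m, 0.6)
  expect_error(meanIoU(numeric(0)), "at least one")
})

test_that("evaluateSet pools confusion counts over images", {
  set.seed(31)
  truths <- lapply(1:4, function(i) randomMask(9, 7))
  preds <- lapply(truths, function(m) {
    p <- m; flip <- sample(length(m), 12); p[flip] <- sample(0:2, 12, TRUE); p
  })
  ev <- evaluateSet(preds, truths)

  # additivity: pooled metrics equal metrics from summed per-image tables
  for (cl in 1:2) {
    tp <- sum(vapply(1:4, function(i) confusionTable(preds[[i]], truths[[i]], cl)$TP, numeric(1)))
    fp <- sum(vapply(1:4, function(i) confusionTable(preds[[i]], truths[[i]], cl)$FP, numeric(1)))
    fn <- sum(vapply(1:4, function(i) confusionTable(preds[[i]], truths[[i]], cl)$FN, numeric(1)))
    expect_equal(ev$perClass$FIOU[cl], tp / (tp + fp + fn))
  }
  # duplicating every pair leaves all metrics unchanged
  ev2 <- evaluateSet(c(preds, preds), c(truths, truths))
  expect_equal(ev2$perClass$F1, ev$perClass$F1)
  expect_equal(ev2$FMIOU, ev$FMIOU)

  perfect <- evaluateSet(truths[1], truths[1])
  expect_true(all(perfect$perClass[, c("P", "R", "F1", "FIOU")] == 1))
  expect_equal(perfect$FMIOU, 1)

  expect_error(evaluateSet(preds, truths[1:2]), "mismatch")
})

test_that("metrics agree exactly with brute-force per-pixel recounts", {
  set.seed(77)
  for (rep in 1:40) {
    truth <- randomMask(8, 8); pred <- randomMask(8, 8)
    bf <- bruteForceMetrics(pred, truth)
    ev <- suppressWarnings(evaluateSet(list(pred), list(truth)))
    for (cl in 1:2) {
      nm <- c("grain", "impurity")[cl]
      expect_equal(ev$perClass$TP[cl], as.numeric(bf[[nm]][["TP"]]))
      expect_equal(ev$perClass$P[cl], bf[[nm]][["P"]])
      expect_equal(ev$perClass$R[cl], bf[[nm]][["R"]])
      expect_equal(ev$perClass$F1[cl], bf[[nm]][["F1"]])
      expect_equal(ev$perClass$FIOU[cl], bf[[nm]][["IOU"]])
    }
    expect_equal(suppressWarnings(ev$FMIOU), bf$MIOU)
  }
})

test_that("metricsReport writes CSV and a readable table", {
  f <- withr::local_tempfile(fileext = ".csv")
  truth <- randomMask(10, 10)
  ev <- suppressWarnings(evaluateSet(list(truth), list(truth)))
  lines <- metricsReport(ev, f, speedMs = 12.5)
  expect_true(file.exists(f))
  csv <- read.csv(f)
  expect_equal(csv$FMIOU[1], 1)
  expect_match(paste(lines, collapse = "\n"), "MIOU")
})
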