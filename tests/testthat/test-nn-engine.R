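# Finite-difference verification of the engine's backward pass. Ops are
# checked in isolation under a smooth quadratic loss (no ReLU kinks), then the
# whole tiny network under its real cross-entropy loss.

ns <- asNamespace("wheatSeg")

opGradError <- function(build, n = 10, cin = 3, seed = 1) {
  set.seed(seed)
  G <- ns$newGraph()
  inId <- ns$addNode(G, "input")
  outId <- build(G, inId)
  x <- matrix(rnorm(n * n * cin), n * n, cin)
  vals <- ns$graphForward(G, ns$tensor(x, n, n))
  y <- vals[[outId]]$x
  tgt <- matrix(0.5 * rnorm(length(y)), nrow(y))
  lossOf <- function() {
    v <- ns$graphForward(G, ns$tensor(x, n, n))
    sum((v[[outId]]$x - tgt)^2) / 2
  }
  ns$zeroGrads(G$params)
  ns$graphBackward(G, vals, y - tgt, outId)
  worst <- 0
  for (p in G$params) for (k in seq_len(min(length(p$w), 15))) {
    w0 <- p$w[k]; eps <- 1e-6
    p$w[k] <- w0 + eps; lp <- lossOf()
    p$w[k] <- w0 - eps; lm <- lossOf()
    p$w[k] <- w0
    num <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(num - p$g[k]) / max(1e-6, abs(num) + abs(p$g[k])))
  }
  worst
}

test_that("conv, depthwise conv, norm and maxpool gradients match finite differences", {
  expect_lt(opGradError(function(G, i)
    ns$addNode(G, "conv", i, ns$convModule(3L, 4L, 3L, 1L, 1L))), 1e-5)
  expect_lt(opGradError(function(G, i)
    ns$addNode(G, "conv", i, ns$convModule(3L, 4L, 3L, 2L, 1L))), 1e-5)
  expect_lt(opGradError(function(G, i)
    ns$addNode(G, "conv", i, ns$convModule(3L, 2L, 7L, 2L, 1L))), 1e-5)
  expect_lt(opGradError(function(G, i)
    ns$addNode(G, "conv", i, ns$convModule(3L, 4L, 3L, 1L, 3L))), 1e-5)
  expect_lt(opGradError(function(G, i)
    ns$addNode(G, "dwconv", i, ns$dwConvModule(3L, 3L, 1L, 2L))), 1e-5)
  expect_lt(opGradError(function(G, i)
    ns$addNode(G, "dwconv", i, ns$dwConvModule(3L, 3L, 2L, 1L))), 1e-5)
  expect_lt(opGradError(function(G, i)
    ns$addNode(G, "norm", i, ns$normModule(3L))), 1e-5)
  expect_lt(opGradError(function(G, i) {
    mp <- ns$addNode(G, "maxpool", i)
    ns$addNode(G, "conv", mp, ns$convModule(3L, 4L, 1L, 1L, 1L))
  }), 1e-5)
})

test_that("upsample, pooling, broadcast, concat and residual-add gradients are exact", {
  expect_lt(opGradError(function(G, i) {
    c1 <- ns$addNode(G, "conv", i, ns$convModule(3L, 4L, 3L, 2L, 1L))
    up <- ns$addNode(G, "upsample", c1)
    G$nodes[[up]]$st$factor <- 2L
    up
  }), 1e-5)
  expect_lt(opGradError(function(G, i) {
    gp <- ns$addNode(G, "gap", i)
    pc <- ns$addNode(G, "conv", gp, ns$convModule(3L, 4L, 1L, 1L, 1L))
    br <- ns$addNode(G, "broadcast", c(pc, i))
    c2 <- ns$addNode(G, "conv", i, ns$convModule(3L, 4L, 1L, 1L, 1L))
    cc <- ns$addNode(G, "concat", c(br, c2))
    ad <- ns$addNode(G, "add", c(cc, cc))
    ns$addNode(G, "conv", ad, ns$convModule(8L, 2L, 1L, 1L, 1L))
  }), 1e-5)
})

test_that("the full tiny network backpropagates correctly", {
  m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
                              inputSize = c(32, 32)), seed = 42)
  set.seed(5)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  lab <- matrix(sample(0:2, 1024, TRUE), 32)
  G <- m@graph
  lossOf <- function() {
    fw <- ns$modelForward(m, img, train = TRUE)
    ns$softmaxXent(fw$logits, as.integer(lab))$loss
  }
  fw <- ns$modelForward(m, img, train = TRUE)
  ce <- ns$softmaxXent(fw$logits, as.integer(lab))
  ns$zeroGrads(G$params)
  ns$graphBackward(G, fw$vals, ce$grad)
  worst <- 0
  set.seed(9)
  for (p in G$params) for (k in sample(length(p$w), min(2, length(p$w)))) {
    w0 <- p$w[k]; eps <- 1e-5
    p$w[k] <- w0 + eps; lp <- lossOf()
    p$w[k] <- w0 - eps; lm <- lossOf()
    p$w[k] <- w0
    num <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(num - p$g[k]) / max(1e-6, abs(num) + abs(p$g[k])))
  }
  expect_lt(worst, 1e-3)
})

test_that("softmax cross-entropy matches a direct computation", {
  set.seed(3)
  logits <- matrix(rnorm(12), 4, 3)
  labels <- c(0L, 2L, 1L, 1L)
  ce <- ns$softmaxXent(logits, labels)
  probs <- exp(logits) / rowSums(exp(logits))
  expect_equal(ce$loss, -mean(log(probs[cbind(1:4, labels + 1L)])),
               tolerance = 1e-12)
  # gradient rows sum to zero (softmax simplex constraint)
  expect_equal(rowSums(ce$grad), rep(0, 4), tolerance = 1e-12)
})

test_that("bilinear interpolation matrices are row-stochastic and exact at identity", {
  M <- ns$interpMatrix(8L, 16L)
  expect_equal(rowSums(M), rep(1, 16), tolerance = 1e-12)
  expect_equal(ns$interpMatrix(6L, 6L), diag(6), tolerance = 1e-12)
})
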