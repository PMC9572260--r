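#' ModelConfig: architecture of the segmentation network
#'
#' The encoder is the chosen backbone with atrous (dilated) convolution
#' replacing the stride of its final stage, followed by atrous spatial
#' pyramid pooling: parallel 3x3 branches at the configured dilation rates,
#' a 1x1 branch and a global image-pooling branch, concatenated and projected
#' by a 1x1 convolution. The decoder bilinearly upsamples the encoder output
#' by 4, concatenates the backbone's output-stride-4 low-level features,
#' refines with 3x3 convolutions and upsamples by 4 again to a per-pixel
#' 3-class score map at input resolution.
#'
#' @slot backbone one of "tiny", "mobilenetv2", "resnet50", "resnet101",
#'   "xception65". The "tiny" backbone is a few width-scaled conv stages for
#'   desk-scale experiments; the others follow their canonical layouts.
#' @slot widthMultiplier channel-width scaling in (0, 1].
#' @slot outputStride encoder output stride, 8 or 16.
#' @slot asppRates dilation rates of the ASPP 3x3 branches.
#' @slot nClasses number of classes (3: background/grain/impurity).
#' @slot inputSize c(height, width); must be divisible by 16.
#' @export
setClass("ModelConfig", representation(
  backbone = "character", widthMultiplier = "numeric",
  outputStride = "integer", asppRates = "integer",
  nClasses = "integer", inputSize = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@backbone %in% c("tiny", "mobilenetv2", "resnet50", "resnet101",
                              "xception65"))
    msg <- c(msg, sprintf("unknown backbone '%s'", object@backbone))
  if (object@widthMultiplier <= 0 || object@widthMultiplier > 1)
    msg <- c(msg, "widthMultiplier must be in (0, 1]")
  if (!object@outputStride %in% c(8L, 16L))
    msg <- c(msg, "outputStride must be 8 or 16")
  if (length(object@asppRates) < 1L || any(object@asppRates < 1L))
    msg <- c(msg, "asppRates must be positive integers")
  if (object@nClasses != 3L)
    msg <- c(msg, "nClasses must be 3 for this task")
  if (length(object@inputSize) != 2L || any(object@inputSize %% 16L != 0L))
    msg <- c(msg, "inputSize must be two multiples of 16")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' Defaults follow the canonical DeepLabV3+ design: output stride 16 with
#' ASPP rates (6, 12, 18), 512 x 512 input, three classes.
#'
#' @param backbone backbone name (see [ModelConfig-class]).
#' @param widthMultiplier channel scaling in (0, 1].
#' @param outputStride 8 or 16.
#' @param asppRates ASPP dilation rates.
#' @param nClasses number of classes (fixed at 3).
#' @param inputSize c(height, width), multiples of 16.
#' @return A [ModelConfig-class] object.
#' @export
ModelConfig <- function(backbone = "resnet50", widthMultiplier = 1,
                        outputStride = 16L, asppRates = c(6L, 12L, 18L),
                        nClasses = 3L, inputSize = c(512L, 512L)) {
  new("ModelConfig", backbone = backbone,
      widthMultiplier = as.numeric(widthMultiplier),
      outputStride = as.integer(outputStride),
      asppRates = as.integer(asppRates), nClasses = as.integer(nClasses),
      inputSize = as.integer(inputSize))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: DeepLabV3+ / %s (width x%.2f), output stride %d, ASPP rates %s, input %dx%d\n",
              object@backbone, object@widthMultiplier, object@outputStride,
              paste(object@asppRates, collapse = ","),
              object@inputSize[1], object@inputSize[2]))
})

#' TrainConfig: optimisation settings
#'
#' @slot epochs number of passes over the training set.
#' @slot batchSize images per optimiser step (gradients averaged).
#' @slot learningRate initial Adam learning rate.
#' @slot lrDecayFactor multiplicative step decay factor.
#' @slot lrDecayEvery epochs between decays.
#' @slot weightDecay L2 penalty coefficient.
#' @slot seed integer seed fixing shuffling (and init when the model is built
#'   with the same seed).
#' @slot init "random" or the path to a checkpoint whose weights initialise
#'   the model (fine-tuning).
#' @slot device "cpu" (the only device this engine supports).
#' @export
setClass("TrainConfig", representation(
  epochs = "integer", batchSize = "integer", learningRate = "numeric",
  lrDecayFactor = "numeric", lrDecayEvery = "integer",
  weightDecay = "numeric", seed = "integer", init = "character",
  device = "character"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@lrDecayFactor <= 0 || object@lrDecayFactor > 1)
    msg <- c(msg, "lrDecayFactor must be in (0, 1]")
  if (object@lrDecayEvery < 1L) msg <- c(msg, "lrDecayEvery must be >= 1")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (!object@device %in% "cpu")
    msg <- c(msg, "this engine runs on 'cpu' only")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#' @param epochs,batchSize,learningRate,lrDecayFactor,lrDecayEvery,weightDecay,seed,init,device
#'   see [TrainConfig-class].
#' @return A [TrainConfig-class] object.
#' @export
TrainConfig <- function(epochs = 10L, batchSize = 4L, learningRate = 3e-3,
                        lrDecayFactor = 0.5, lrDecayEvery = 5L,
                        weightDecay = 1e-5, seed = 1L, init = "random",
                        device = "cpu") {
  new("TrainConfig", epochs = assertCount(epochs, "epochs"),
      batchSize = assertCount(batchSize, "batchSize"),
      learningRate = as.numeric(learningRate),
      lrDecayFactor = as.numeric(lrDecayFactor),
      lrDecayEvery = assertCount(lrDecayEvery, "lrDecayEvery"),
      weightDecay = as.numeric(weightDecay),
      seed = assertCount(seed, "seed"), init = init, device = device)
}

#' SegModel: a built (possibly trained) segmentation network
#'
#' @slot config the [ModelConfig-class].
#' @slot graph internal computation graph (environment; treat as opaque).
#' @slot history per-epoch training log (epoch, loss, lr, valMIOU).
#' @slot seed the seed the parameters were initialised with.
#' @export
setClass("SegModel", representation(
  config = "ModelConfig", graph = "environment", history = "data.frame",
  seed = "integer"))

setMethod("show", "SegModel", function(object) {
  np <- sum(vapply(object@graph$params, function(p) length(p$w), numeric(1)))
  cat(sprintf("SegModel: DeepLabV3+ / %s, %s parameters, %d training epochs recorded\n",
              object@config@backbone, format(np, big.mark = ","),
              nrow(object@history)))
})

#' @describeIn SegModel the architecture configuration.
#' @param model a SegModel.
#' @export
modelConfig <- function(model) { stopifnot(is(model, "SegModel")); model@config }

#' @describeIn SegModel the per-epoch training history.
#' @export
trainHistory <- function(model) { stopifnot(is(model, "SegModel")); model@history }

## ---- construction -----------------------------------------------------------

addDeepLabHead <- function(G, bk, config) {
  wm <- config@widthMultiplier
  Ca <- scaledCh(256, wm)
  branches <- c(
    cbr(G, bk$encId, bk$encCh, Ca, 1L),
    vapply(config@asppRates, function(r)
      cbr(G, bk$encId, bk$encCh, Ca, 3L, 1L, r), integer(1)))
  gp <- addNode(G, "gap", bk$encId)
  pc <- addNode(G, "conv", gp, convModule(bk$encCh, Ca, 1L))
  pr <- addNode(G, "relu", pc)
  bc <- addNode(G, "broadcast", c(pr, bk$encId))
  cc <- addNode(G, "concat", c(branches, bc))
  proj <- cbr(G, cc, Ca * (length(branches) + 1L), Ca, 1L)
  upF <- config@outputStride %/% 4L
  up1 <- addNode(G, "upsample", proj); G$nodes[[up1]]$st$factor <- upF
  lowP <- cbr(G, bk$lowId, bk$lowCh, scaledCh(48, wm), 1L)
  cat2 <- addNode(G, "concat", c(up1, lowP))
  d1 <- cbr(G, cat2, Ca + scaledCh(48, wm), Ca, 3L)
  d2 <- cbr(G, d1, Ca, Ca, 3L)
  cls <- addNode(G, "conv", d2, convModule(Ca, config@nClasses, 1L))
  out <- addNode(G, "upsample", cls); G$nodes[[out]]$st$factor <- 4L
  out
}

#' Build a DeepLabV3+ segmentation model
#'
#' Constructs the encoder (backbone with an atrous final stage + ASPP) and
#' decoder on the package's CPU engine and initialises all weights (He
#' normal) from `seed`: two builds with the same config and seed have
#' identical parameters.
#'
#' @param config a [ModelConfig()].
#' @param seed integer seed for weight initialisation.
#' @return A [SegModel-class].
#' @examples
#' m <- buildModel(ModelConfig("tiny", widthMultiplier = 0.25,
#'                             inputSize = c(64, 64)), seed = 1)
#' dim(predictMask(m, renderScene(SceneSpec(64, 64, 20, 2, seed = 3))@image))
#' @export
buildModel <- function(config, seed = 1L) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  seed <- assertCount(seed, "seed")
  withSeed(seed, {
    G <- newGraph()
    inId <- addNode(G, "input")
    bk <- buildBackbone(G, inId, config@backbone, config@widthMultiplier,
                        config@outputStride)
    addDeepLabHead(G, bk, config)
    new("SegModel", config = config, graph = G,
        history = data.frame(epoch = integer(0), loss = numeric(0),
                             lr = numeric(0), valMIOU = numeric(0)),
        seed = seed)
  })
}

imageToTensor <- function(image) {
  d <- dim(image)
  tensor(matrix(as.numeric(image), d[1] * d[2], d[3]), d[1], d[2])
}

## Forward pass to logits; returns list(vals, logits matrix HW x nClasses).
modelForward <- function(model, image, train = FALSE) {
  d <- dim(image)
  sz <- model@config@inputSize
  if (length(d) != 3L || d[1] != sz[1] || d[2] != sz[2] || d[3] != 3L)
    stop(sprintf("image must be %d x %d x 3 for this model (got %s); resize with resizePair()",
                 sz[1], sz[2], paste(d, collapse = "x")), call. = FALSE)
  vals <- graphForward(model@graph, imageToTensor(image), train)
  list(vals = vals, logits = vals[[length(vals)]]$x)
}

#' Predict a label mask for one image
#'
#' Runs the network and takes the per-pixel argmax over the 3 class scores.
#' Deterministic: repeated calls on the same image give identical masks
#' (argmax ties break to the lower class index).
#'
#' @param model a trained or freshly built [SegModel-class].
#' @param image numeric array [H, W, 3] matching the model's `inputSize`.
#' @return Integer label mask [H, W] with values in \{0, 1, 2\}.
#' @export
predictMask <- function(model, image) {
  stopifnot(is(model, "SegModel"))
  fw <- modelForward(model, image, train = FALSE)
  lab <- max.col(fw$logits, ties.method = "first") - 1L
  matrix(as.integer(lab), nrow = model@config@inputSize[1])
}

#' Mean per-image inference time
#'
#' Wall-clock milliseconds per image, averaged over the supplied images.
#' Reported for orientation only; absolute values depend entirely on the
#' hardware and BLAS in use.
#'
#' @param model a [SegModel-class].
#' @param images list of image arrays.
#' @return Mean milliseconds per image, with attribute `"hardware"` noting
#'   the platform.
#' @export
measureSpeed <- function(model, images) {
  stopifnot(is(model, "SegModel"), length(images) >= 1L)
  ms <- vapply(images, function(img) {
    1000 * unname(system.time(predictMask(model, img))["elapsed"])
  }, numeric(1))
  structure(mean(ms), hardware = paste(R.version$platform, "CPU"))
}

## ---- checkpoints -------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: architecture config, all weights, the
#' training history and the init seed, serialised with `saveRDS`.
#'
#' @param model a [SegModel-class].
#' @param path checkpoint file path.
#' @return `loadCheckpoint` returns the restored [SegModel-class];
#'   `saveCheckpoint` returns `path` invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "SegModel"))
  cfg <- model@config
  saveRDS(list(
    config = list(backbone = cfg@backbone, widthMultiplier = cfg@widthMultiplier,
                  outputStride = cfg@outputStride, asppRates = cfg@asppRates,
                  nClasses = cfg@nClasses, inputSize = cfg@inputSize),
    weights = lapply(model@graph$params, function(p) p$w),
    history = model@history, seed = model@seed), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(ModelConfig, ck$config)
  model <- buildModel(cfg, seed = ck$seed)
  setModelWeights(model, ck$weights)
  model@history <- ck$history
  model
}

setModelWeights <- function(model, weights) {
  ps <- model@graph$params
  if (length(ps) != length(weights))
    stop("checkpoint weights do not match the model architecture", call. = FALSE)
  for (i in seq_along(ps)) ps[[i]]$w <- weights[[i]]
  invisible(model)
}

getModelWeights <- function(model) lapply(model@graph$params, function(p) p$w)
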