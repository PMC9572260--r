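#' Train a segmentation model
#'
#' Minimises unweighted per-pixel 3-class cross-entropy with Adam over the
#' training pairs, shuffling each epoch under the config seed, with a step-
#' decayed learning rate. After each epoch the validation MIOU (two-class
#' mean intersection-over-union, grain and impurity) is computed and the
#' best-on-validation weights are retained in the returned model.
#'
#' @param model a [SegModel-class] from [buildModel()].
#' @param trainSet,valSet lists of pairs `list(image =, mask =)` at the
#'   model's input size (e.g. from [loadDataset()]); `valSet` may be NULL.
#' @param config a [TrainConfig()].
#' @param verbose print one line per epoch.
#' @return The trained [SegModel-class] with its `history` slot filled
#'   (columns epoch, loss, lr, valMIOU).
#' @export
trainModel <- function(model, trainSet, valSet = NULL, config = TrainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "SegModel"), is(config, "TrainConfig"))
  validObject(config)
  if (config@epochs == 0L) return(model)
  if (!length(trainSet)) stop("empty training set", call. = FALSE)
  if (config@init != "random") {
    if (!file.exists(config@init))
      stop(sprintf("init checkpoint '%s' not found", config@init), call. = FALSE)
    setModelWeights(model, readRDS(config@init)$weights)
  }
  G <- model@graph
  nc <- model@config@nClasses
  hist <- vector("list", config@epochs)
  bestMiou <- -Inf; bestW <- NULL
  step <- 0L
  withSeed(config@seed, {
    for (ep in seq_len(config@epochs)) {
      lr <- config@learningRate *
        config@lrDecayFactor^((ep - 1L) %/% config@lrDecayEvery)
      ord <- sample.int(length(trainSet))
      zeroGrads(G$params)
      nAcc <- 0L
      losses <- numeric(length(ord))
      for (j in seq_along(ord)) {
        p <- trainSet[[ord[j]]]
        fw <- modelForward(model, p$image, train = TRUE)
        ce <- softmaxXent(fw$logits, as.integer(p$mask))
        if (!is.finite(ce$loss))
          stop(sprintf("non-finite loss at epoch %d, image %d (lr %.3g): try a lower learning rate",
                       ep, j, lr), call. = FALSE)
        losses[j] <- ce$loss
        graphBackward(G, fw$vals, ce$grad)
        nAcc <- nAcc + 1L
        if (nAcc == config@batchSize || j == length(ord)) {
          for (q in G$params) q$g <- q$g / nAcc
          step <- step + 1L
          adamStep(G$params, lr, step, weightDecay = config@weightDecay)
          zeroGrads(G$params)
          nAcc <- 0L
        }
      }
      valMiou <- NA_real_
      if (length(valSet)) {
        preds <- lapply(valSet, function(v) predictMask(model, v$image))
        truths <- lapply(valSet, `[[`, "mask")
        valMiou <- evaluateSet(preds, truths)$FMIOU
        if (is.finite(valMiou) && valMiou > bestMiou) {
          bestMiou <- valMiou
          bestW <- getModelWeights(model)
        }
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = mean(losses), lr = lr,
                               valMIOU = valMiou)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, lr %.4g, val MIOU %s",
                        ep, mean(losses), lr,
                        ifelse(is.na(valMiou), "-", sprintf("%.4f", valMiou))))
    }
  })
  if (!is.null(bestW)) setModelWeights(model, bestW)
  model@history <- rbind(model@history, do.call(rbind, hist))
  model
}
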