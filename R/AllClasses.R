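#' @import methods
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv modifyList head packageVersion
NULL

## Conventions used throughout the package:
##  * images are numeric arrays [H, W, 3] with values in [0, 1]
##  * label masks are integer matrices [H, W] over {0 background, 1 grain,
##    2 impurity}
##  * polygon vertices are 0-based (x right, y down); the centre of matrix
##    cell (r, c) sits at x = c - 0.5, y = r - 0.5

setClassUnion("listOrNULL", c("list", "NULL"))

#' SceneSpec: parameters of a synthetic grain-pile scene
#'
#' Describes one synthetic image of a wheat pile on the dark floor of a
#' sampling bin: how many grains (filled ellipses) and impurities (bent
#' straw strips and thin husk arcs) to draw, their size ranges in pixels,
#' base RGB colours with jitter, and the camera-noise model. The same spec
#' plus seed always renders bit-for-bit the same sample.
#'
#' @slot width,height canvas size in pixels.
#' @slot nGrains,nImpurities object counts (>= 0).
#' @slot grainAxisRange length-2 range of ellipse semi-axes in pixels.
#' @slot impurityLengthRange,impurityWidthRange strip length/width ranges.
#' @slot grainColor,impurityColor,backgroundColor base RGB in [0,1].
#' @slot colorJitterSd per-object RGB jitter standard deviation.
#' @slot blurSigma Gaussian blur sigma in pixels (0 disables).
#' @slot noiseSd additive pixel noise standard deviation (0 disables).
#' @slot seed integer seed fixing the render.
#' @export
setClass("SceneSpec", representation(
  width = "integer", height = "integer",
  nGrains = "integer", nImpurities = "integer",
  grainAxisRange = "numeric",
  impurityLengthRange = "numeric", impurityWidthRange = "numeric",
  grainColor = "numeric", impurityColor = "numeric",
  backgroundColor = "numeric",
  colorJitterSd = "numeric", blurSigma = "numeric", noiseSd = "numeric",
  seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@width < 8L || object@height < 8L)
    msg <- c(msg, "canvas must be at least 8x8 pixels")
  if (object@nGrains < 0L || object@nImpurities < 0L)
    msg <- c(msg, "object counts must be >= 0")
  rngs <- list(grainAxisRange = object@grainAxisRange,
               impurityLengthRange = object@impurityLengthRange,
               impurityWidthRange = object@impurityWidthRange)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] <= 0 || r[2] < r[1])
      msg <- c(msg, sprintf("%s must be an increasing positive length-2 range", nm))
  }
  lim <- min(object@width, object@height)
  if (2 * max(object@grainAxisRange) >= lim)
    msg <- c(msg, "grains too large for the canvas")
  if (max(object@impurityLengthRange) >= lim)
    msg <- c(msg, "impurities too long for the canvas")
  for (nm in c("grainColor", "impurityColor", "backgroundColor")) {
    cl <- slot(object, nm)
    if (length(cl) != 3L || any(cl < 0) || any(cl > 1))
      msg <- c(msg, sprintf("%s must be an RGB triplet in [0,1]", nm))
  }
  if (object@colorJitterSd < 0 || object@blurSigma < 0 || object@noiseSd < 0)
    msg <- c(msg, "jitter/blur/noise parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' Defaults emulate a pile of wheat grains (warm ochre ellipses) with sparse
#' straw/husk impurities (pale yellow elongated fragments) on the dark bin
#' background, at the working resolution of the detection pipeline.
#'
#' @param width,height canvas size in pixels.
#' @param nGrains,nImpurities number of grains / impurity fragments.
#' @param grainAxisRange range of grain ellipse semi-axes (pixels).
#' @param impurityLengthRange,impurityWidthRange straw strip geometry (pixels).
#' @param grainColor,impurityColor,backgroundColor base RGB triplets in [0,1].
#' @param colorJitterSd per-object colour jitter SD.
#' @param blurSigma Gaussian blur sigma (pixels).
#' @param noiseSd additive Gaussian pixel noise SD.
#' @param seed integer seed; fixes the render bit-for-bit.
#' @return A [SceneSpec-class] object.
#' @examples
#' spec <- SceneSpec(width = 96, height = 96, nGrains = 40, seed = 1)
#' sample <- renderScene(spec)
#' @export
SceneSpec <- function(width = 512L, height = 512L,
                      nGrains = 900L, nImpurities = 18L,
                      grainAxisRange = c(5, 11) * width / 512,
                      impurityLengthRange = c(40, 110) * width / 512,
                      impurityWidthRange = c(4, 9) * width / 512,
                      grainColor = c(0.72, 0.54, 0.33),
                      impurityColor = c(0.86, 0.82, 0.58),
                      backgroundColor = c(0.10, 0.09, 0.08),
                      colorJitterSd = 0.04,
                      blurSigma = 0.6, noiseSd = 0.015,
                      seed = 1L) {
  new("SceneSpec",
      width = assertCount(width, "width"), height = assertCount(height, "height"),
      nGrains = assertCount(nGrains, "nGrains"),
      nImpurities = assertCount(nImpurities, "nImpurities"),
      grainAxisRange = as.numeric(grainAxisRange),
      impurityLengthRange = as.numeric(impurityLengthRange),
      impurityWidthRange = as.numeric(impurityWidthRange),
      grainColor = as.numeric(grainColor),
      impurityColor = as.numeric(impurityColor),
      backgroundColor = as.numeric(backgroundColor),
      colorJitterSd = as.numeric(colorJitterSd),
      blurSigma = as.numeric(blurSigma), noiseSd = as.numeric(noiseSd),
      seed = assertCount(seed, "seed"))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec %dx%d: %d grains, %d impurities (seed %d)\n",
              object@width, object@height, object@nGrains,
              object@nImpurities, object@seed))
})

#' MassModel: per-1000-pixel mass densities
#'
#' Converts pixel areas into grams: the mass of grain (or impurity) visible in
#' an image is its pixel count / 1000 times the class density, optionally
#' perturbed by multiplicative Gaussian noise with coefficient of variation
#' `noiseCv` (emulating weighing and sampling error). The implied true
#' grain-to-impurity mass ratio at equal pixel area is
#' `grainMassPerKpx / impurityMassPerKpx`.
#'
#' @slot grainMassPerKpx grams of grain per 1000 grain pixels.
#' @slot impurityMassPerKpx grams of impurity per 1000 impurity pixels.
#' @slot noiseCv coefficient of variation of the multiplicative mass noise.
#' @export
setClass("MassModel", representation(
  grainMassPerKpx = "numeric", impurityMassPerKpx = "numeric",
  noiseCv = "numeric"))

setValidity("MassModel", function(object) {
  if (object@grainMassPerKpx <= 0 || object@impurityMassPerKpx <= 0)
    return("mass densities must be > 0")
  if (object@noiseCv < 0) return("noiseCv must be >= 0")
  TRUE
})

#' Construct a MassModel
#'
#' The default density ratio equals the laboratory-calibrated grain-to-
#' impurity mass ratio of 11.8906 used by the quantification model, so
#' noiseless synthetic data reproduce the mass-based impurity rate exactly.
#'
#' @param grainMassPerKpx grams per 1000 grain pixels.
#' @param impurityMassPerKpx grams per 1000 impurity pixels.
#' @param noiseCv multiplicative noise CV (fraction).
#' @return A [MassModel-class] object.
#' @export
MassModel <- function(grainMassPerKpx = 2.14,
                      impurityMassPerKpx = 2.14 / defaultDelta(),
                      noiseCv = 0) {
  new("MassModel", grainMassPerKpx = as.numeric(grainMassPerKpx),
      impurityMassPerKpx = as.numeric(impurityMassPerKpx),
      noiseCv = as.numeric(noiseCv))
}

#' @describeIn MassModel implied true grain/impurity mass ratio.
#' @param model a MassModel.
#' @export
trueDelta <- function(model) {
  stopifnot(is(model, "MassModel"))
  model@grainMassPerKpx / model@impurityMassPerKpx
}

setMethod("show", "MassModel", function(object) {
  cat(sprintf("MassModel: grain %.4g g/kpx, impurity %.4g g/kpx (delta = %.4f), noise CV %.3g\n",
              object@grainMassPerKpx, object@impurityMassPerKpx,
              trueDelta(object), object@noiseCv))
})

#' RenderedSample: one synthetic scene with exact ground truth
#'
#' @slot image numeric array [H, W, 3] in [0, 1].
#' @slot mask integer matrix [H, W] with labels 0/1/2.
#' @slot trueCounts named integer vector c(Tw = grain pixels, Tz = impurity pixels).
#' @slot polygons list of lists with elements `label` ("grain"/"impurity") and
#'   `points` (n x 2 matrix of 0-based x,y vertices).
#' @export
setClass("RenderedSample", representation(
  image = "array", mask = "matrix", trueCounts = "integer",
  polygons = "list"))

setValidity("RenderedSample", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "image must be [H, W, 3]")
  if (!identical(dim(object@mask), d[1:2]))
    msg <- c(msg, "mask and image dimensions differ")
  if (!all(object@mask %in% 0:2)) msg <- c(msg, "mask labels outside {0,1,2}")
  tw <- sum(object@mask == 1L); tz <- sum(object@mask == 2L)
  if (!identical(unname(object@trueCounts), c(tw, tz)))
    msg <- c(msg, "trueCounts do not match the mask tally")
  bad <- vapply(object@polygons,
                function(p) !p$label %in% c("grain", "impurity"),
                logical(1))
  if (any(bad)) msg <- c(msg, "polygon labels must be 'grain' or 'impurity'")
  if (length(msg)) msg else TRUE
})

#' @describeIn RenderedSample the rendered RGB image.
#' @param x a RenderedSample.
#' @export
imageOf <- function(x) { stopifnot(is(x, "RenderedSample")); x@image }

#' @describeIn RenderedSample the ground-truth label mask.
#' @export
maskOf <- function(x) { stopifnot(is(x, "RenderedSample")); x@mask }

#' @describeIn RenderedSample named grain/impurity pixel tallies (Tw, Tz).
#' @export
trueCounts <- function(x) { stopifnot(is(x, "RenderedSample")); x@trueCounts }

#' @describeIn RenderedSample the labelled outline polygons.
#' @export
polygonsOf <- function(x) { stopifnot(is(x, "RenderedSample")); x@polygons }

setMethod("show", "RenderedSample", function(object) {
  d <- dim(object@mask)
  cat(sprintf("RenderedSample %dx%d: Tw = %d grain px, Tz = %d impurity px, %d polygons\n",
              d[1], d[2], object@trueCounts[["Tw"]], object@trueCounts[["Tz"]],
              length(object@polygons)))
})

#' TrialSeries: paired device / manual impurity-rate measurements
#'
#' One batch (bench test) or harvester trip (field test): the repeated
#' impurity rates reported by the online device and the manual reference
#' measurements from weighed samples, all in percent.
#'
#' @slot device device detections P_Sz,i in percent.
#' @slot manual manual measurements P_Mz,i in percent.
#' @slot label batch/trip identifier.
#' @export
setClass("TrialSeries", representation(
  device = "numeric", manual = "numeric", label = "character"))

setValidity("TrialSeries", function(object) {
  msg <- character()
  if (!length(object@device) || !length(object@manual))
    msg <- c(msg, "device and manual series must be non-empty")
  vals <- c(object@device, object@manual)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100))
    msg <- c(msg, "rates must be finite percentages in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct a TrialSeries
#' @param device numeric vector of device detections (percent).
#' @param manual numeric vector of manual measurements (percent).
#' @param label identifier for the batch or trip.
#' @return A [TrialSeries-class] object.
#' @export
TrialSeries <- function(device, manual, label = "trial") {
  new("TrialSeries", device = as.numeric(device),
      manual = as.numeric(manual), label = as.character(label)[1])
}

setMethod("show", "TrialSeries", function(object) {
  cat(sprintf("TrialSeries '%s': %d device detections (mean %.3f%%), %d manual samples (mean %.3f%%)\n",
              object@label, length(object@device), mean(object@device),
              length(object@manual), mean(object@manual)))
})
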