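## Impurity-rate quantification: converting segmented pixel counts into the
## mass-based impurity rate via the calibrated grain-to-impurity mass ratio.

#' Default grain-to-impurity mass ratio
#'
#' The laboratory-calibrated ratio of the average mass of grain to the
#' average mass of impurity covering 1000 pixels each: 11.8906. Shipped as a
#' documented default; recalibrate with [calibrateDelta()] for a different
#' crop, camera geometry or moisture level.
#'
#' @return The default delta (dimensionless).
#' @export
defaultDelta <- function() 11.8906

#' Manual (mass-based) impurity rate
#'
#' The reference measurement: impurity mass over total sample mass, in
#' percent.
#'
#' @param wz impurity mass in grams.
#' @param w total sample mass in grams (> 0, >= wz).
#' @return Impurity rate in percent.
#' @examples
#' manualRate(5, 500)   # 1%
#' @export
manualRate <- function(wz, w) {
  assertScalarNumber(w, "w", lower = 0, strict_lower = TRUE)
  assertScalarNumber(wz, "wz", lower = 0)
  if (wz > w) stop("impurity mass wz exceeds sample mass w", call. = FALSE)
  wz / w * 100
}

#' Pixel-based impurity rate
#'
#' The quantification model: with Tw grain pixels, Tz impurity pixels and
#' mass ratio delta, the impurity rate is `Tz / (Tz + delta * Tw) * 100` —
#' the pixel areas are converted to masses via the per-1000-pixel densities,
#' whose ratio is delta.
#'
#' @param counts named vector/list with `Tw` (grain pixels) and `Tz`
#'   (impurity pixels).
#' @param delta grain-to-impurity mass ratio (> 0), default [defaultDelta()].
#' @return Impurity rate in percent, or the undefined marker (NA, with a
#'   warning) when the image contains neither grain nor impurity pixels.
#' @examples
#' pixelRate(c(Tw = 10000, Tz = 1000))   # 0.8340 % with the default delta
#' @export
pixelRate <- function(counts, delta = defaultDelta()) {
  tw <- assertCount(counts[["Tw"]], "Tw")
  tz <- assertCount(counts[["Tz"]], "Tz")
  assertScalarNumber(delta, "delta", lower = 0, strict_lower = TRUE)
  if (tw + tz == 0L) {
    warning("impurity rate undefined: no grain or impurity pixels in the image",
            call. = FALSE)
    return(undefinedValue())
  }
  tz / (tz + delta * tw) * 100
}

#' Calibrate the grain-to-impurity mass ratio
#'
#' Estimates delta from paired pixel counts and weighed masses. Each sample
#' contributes a grain density `1000 * (w - wz) / Tw` (when it has grain
#' pixels and grain mass) and an impurity density `1000 * wz / Tz` (when it
#' has impurity pixels and impurity mass). By default delta is the ratio of
#' the mean grain density to the mean impurity density (ratio of means),
#' which stays stable when individual samples have few impurity pixels; the
#' mean of per-sample ratios is available via `method = "mean-of-ratios"`
#' (it needs both components in every sample). The per-sample density spread
#' is reported as a coefficient-of-variation diagnostic.
#'
#' @param samples list of calibration samples, each a list with `counts`
#'   (named vector with Tw, Tz), `w` (total grams), `wz` (impurity grams).
#' @param method "ratio-of-means" (default) or "mean-of-ratios".
#' @return List with `delta`, `nSamples`, `dispersion` (named CV fractions of
#'   the per-sample grain and impurity densities) and `method`.
#' @examples
#' s <- list(list(counts = c(Tw = 1000, Tz = 1000), w = 3, wz = 1))
#' calibrateDelta(s)$delta   # 2
#' @export
calibrateDelta <- function(samples, method = c("ratio-of-means",
                                               "mean-of-ratios")) {
  method <- match.arg(method)
  if (!length(samples)) stop("no calibration samples", call. = FALSE)
  grainD <- impD <- rep(NA_real_, length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    tw <- s$counts[["Tw"]]; tz <- s$counts[["Tz"]]
    if (s$wz < 0 || s$wz > s$w)
      stop(sprintf("sample %d: need 0 <= wz <= w", i), call. = FALSE)
    if (tw > 0 && s$w - s$wz > 0) grainD[i] <- 1000 * (s$w - s$wz) / tw
    if (tz > 0 && s$wz > 0) impD[i] <- 1000 * s$wz / tz
  }
  if (all(is.na(grainD)))
    stop("no usable sample for the grain component (need Tw > 0 and grain mass > 0)",
         call. = FALSE)
  if (all(is.na(impD)))
    stop("no usable sample for the impurity component (need Tz > 0 and wz > 0)",
         call. = FALSE)
  delta <- if (method == "ratio-of-means") {
    mean(grainD, na.rm = TRUE) / mean(impD, na.rm = TRUE)
  } else {
    both <- !is.na(grainD) & !is.na(impD)
    if (!any(both))
      stop("mean-of-ratios needs samples with both components", call. = FALSE)
    mean(grainD[both] / impD[both])
  }
  cv <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    sd(x) / mean(x)
  }
  list(delta = delta, nSamples = length(samples),
       dispersion = c(grain = cv(grainD), impurity = cv(impD)),
       method = method)
}

#' Write / read a calibration file
#'
#' @param calibration result of [calibrateDelta()].
#' @param path JSON file path.
#' @param note free-text provenance note.
#' @return `readCalibration` returns the calibration list; the writer returns
#'   `path` invisibly.
#' @export
writeCalibration <- function(calibration, path, note = "") {
  out <- calibration
  out$note <- note
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  if (!file.exists(path))
    stop(sprintf("calibration file '%s' not found", path), call. = FALSE)
  cal <- jsonlite::fromJSON(path)
  if (is.null(cal$delta) || cal$delta <= 0)
    stop(sprintf("'%s' does not contain a positive delta", path), call. = FALSE)
  cal
}

#' Detect the impurity rate in one image
#'
#' The online-detection step: segment the image, tally grain (label 1) and
#' impurity (label 2) pixels, and convert to an impurity rate with
#' [pixelRate()]. An all-background prediction yields the undefined marker
#' (a frame with no visible grain is a sampling failure, not a 100% impurity
#' reading).
#'
#' @param image numeric array [H, W, 3] at the model's input size.
#' @param model a trained [SegModel-class].
#' @param delta calibrated mass ratio.
#' @param imageId identifier recorded in the detection record.
#' @return List (one detection record): `imageId`, `Tw`, `Tz`, `delta`,
#'   `Pz` (percent or NA), `timestamp`.
#' @export
detectImpurity <- function(image, model, delta = defaultDelta(),
                           imageId = "image") {
  mask <- predictMask(model, image)
  counts <- c(Tw = sum(mask == 1L), Tz = sum(mask == 2L))
  pz <- if (sum(counts) == 0L) {
    warning(sprintf("'%s': all-background prediction, impurity rate undefined",
                    imageId), call. = FALSE)
    undefinedValue()
  } else pixelRate(counts, delta)
  list(imageId = imageId, Tw = unname(counts[["Tw"]]), Tz = unname(counts[["Tz"]]),
       delta = delta, Pz = pz, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Append detection records to a CSV log
#'
#' @param records list of records from [detectImpurity()].
#' @param path CSV path (appended to if it exists).
#' @return The combined data frame, invisibly.
#' @export
writeDetectionLog <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(imageId = r$imageId, Tw = r$Tw, Tz = r$Tz, delta = r$delta,
               Pz = r$Pz, timestamp = r$timestamp)))
  if (file.exists(path)) df <- rbind(read.csv(path, stringsAsFactors = FALSE), df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
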