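## Bench/field trial error statistics: how well the online device tracks the
## manual reference measurement over repeated detections.

#' Absolute error between device and manual means
#'
#' Absolute difference of the mean device detection and the mean manual
#' measurement, in percentage points.
#'
#' @param meanDevice,meanManual mean impurity rates in percent.
#' @return Absolute error in percentage points.
#' @export
absoluteError <- function(meanDevice, meanManual) {
  assertScalarNumber(meanDevice, "meanDevice")
  assertScalarNumber(meanManual, "meanManual")
  abs(meanDevice - meanManual)
}

#' Relative error between device and manual means
#'
#' `|meanDevice - meanManual| / meanManual * 100`.
#'
#' @param meanDevice,meanManual mean impurity rates in percent;
#'   `meanManual` must be > 0.
#' @return Relative error in percent.
#' @examples
#' relativeError(0.92, 1.03)   # 10.68%
#' @export
relativeError <- function(meanDevice, meanManual) {
  assertScalarNumber(meanDevice, "meanDevice")
  assertScalarNumber(meanManual, "meanManual", lower = 0, strict_lower = TRUE)
  abs(meanDevice - meanManual) / meanManual * 100
}

#' Coefficient of variation of a measurement series
#'
#' Sample standard deviation (divisor N-1) over the mean, in percent.
#' Scale-invariant: CV(k x) = CV(x) for k > 0.
#'
#' @param series numeric vector, length >= 2, positive mean.
#' @return CV in percent.
#' @examples
#' coefficientOfVariation(c(1, 3))   # 70.71%
#' @export
coefficientOfVariation <- function(series) {
  if (length(series) < 2L)
    stop("coefficient of variation needs at least 2 values", call. = FALSE)
  m <- mean(series)
  if (m <= 0) stop("coefficient of variation undefined for non-positive mean",
                   call. = FALSE)
  sd(series) / m * 100
}

#' Summarise one trial (bench batch or field trip)
#'
#' Computes the full error-statistics row for one [TrialSeries()]: device and
#' manual means, their coefficients of variation, and the absolute and
#' relative errors of the device against the manual reference.
#'
#' @param series a [TrialSeries()].
#' @return One-row data.frame with columns `label`, `meanDevice`,
#'   `meanManual`, `RScv`, `RMcv`, `Raz`, `Rrz` (all in percent).
#' @export
summarizeTrial <- function(series) {
  stopifnot(is(series, "TrialSeries"))
  validObject(series)
  md <- mean(series@device); mm <- mean(series@manual)
  data.frame(
    label = series@label, meanDevice = md, meanManual = mm,
    RScv = if (length(series@device) >= 2L) coefficientOfVariation(series@device)
           else NA_real_,
    RMcv = if (length(series@manual) >= 2L) coefficientOfVariation(series@manual)
           else NA_real_,
    Raz = absoluteError(md, mm),
    Rrz = relativeError(md, mm))
}

#' Trial report over several batches/trips
#'
#' @param seriesList list of [TrialSeries()] objects.
#' @param csvPath optional CSV output path.
#' @return Data frame with one [summarizeTrial()] row per series.
#' @export
trialReport <- function(seriesList, csvPath = NULL) {
  df <- do.call(rbind, lapply(seriesList, summarizeTrial))
  if (!is.null(csvPath)) write.csv(df, csvPath, row.names = FALSE)
  df
}
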