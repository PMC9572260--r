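## Per-class pixel metrics for segmentation quality.
##
## All metrics derive from per-class pixel confusion counts:
##   P = TP/(TP+FP),  R = TP/(TP+FN),  F1 = 2PR/(P+R),  IOU = TP/(TP+FP+FN),
##   MIOU = mean of the per-class IOUs over the evaluated classes.
## Background is excluded from MIOU: only grain (1) and impurity (2) are
## averaged. Zero denominators yield an explicit undefined marker (NA) with a
## warning, never a silent zero, and undefined values are dropped from means.

#' Per-class pixel confusion counts
#'
#' @param pred,truth integer label masks of identical shape over \{0,1,2\}.
#' @param classId class to evaluate (1 grain or 2 impurity; 0 allowed).
#' @return List with `classId`, `TP`, `FP`, `FN` (pixel counts).
#' @examples
#' truth <- matrix(c(1,1,0,0), 2); pred <- matrix(c(1,0,1,0), 2)
#' confusionTable(pred, truth, 1)
#' @export
confusionTable <- function(pred, truth, classId) {
  assertMask(pred, "pred"); assertMask(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(truth), collapse = "x")), call. = FALSE)
  stopifnot(classId %in% 0:2)
  pc <- pred == classId; tc <- truth == classId
  list(classId = as.integer(classId),
       TP = sum(pc & tc), FP = sum(pc & !tc), FN = sum(!pc & tc))
}

ratioOrUndefined <- function(num, den, what) {
  if (den <= 0) {
    warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
    return(undefinedValue())
  }
  num / den
}

#' Precision, recall, F1 and IOU from confusion counts
#'
#' @param tab a [confusionTable()] result.
#' @param P,R precision and recall as fractions in (0, 1].
#' @return A fraction in [0, 1], or NA (undefined marker) when the
#'   denominator is zero.
#' @name classMetrics
NULL

#' @rdname classMetrics
#' @export
pixelPrecision <- function(tab)
  ratioOrUndefined(tab$TP, tab$TP + tab$FP, "precision")

#' @rdname classMetrics
#' @export
pixelRecall <- function(tab)
  ratioOrUndefined(tab$TP, tab$TP + tab$FN, "recall")

#' @rdname classMetrics
#' @export
f1Score <- function(P, R) {
  if (isUndefined(P) || isUndefined(R)) return(undefinedValue())
  ratioOrUndefined(2 * P * R, P + R, "F1")
}

#' @rdname classMetrics
#' @export
iouScore <- function(tab)
  ratioOrUndefined(tab$TP, tab$TP + tab$FN + tab$FP, "IOU")

#' F1 and IOU from printed precision/recall
#'
#' The identity route used to verify published result tables when the raw
#' masks are unavailable: F1 = 2PR/(P+R) and, algebraically,
#' IOU = PR/(P+R-PR).
#'
#' @param P,R precision and recall as fractions in (0, 1].
#' @return Named numeric vector `c(F1 =, FIOU =)`; NA markers if P or R is 0
#'   or undefined.
#' @examples
#' metricsFromPR(0.8686, 0.8063)   # F1 0.8363, IOU 0.7186
#' @export
metricsFromPR <- function(P, R) {
  if (isUndefined(P) || isUndefined(R) || P <= 0 || R <= 0) {
    warning("F1/IOU undefined for zero precision or recall", call. = FALSE)
    return(c(F1 = undefinedValue(), FIOU = undefinedValue()))
  }
  stopifnot(P <= 1, R <= 1)
  c(F1 = 2 * P * R / (P + R), FIOU = P * R / (P + R - P * R))
}

#' Mean intersection-over-union
#'
#' Arithmetic mean of per-class IOUs. For this task the mean is taken over
#' the two foreground classes (grain, impurity); background is excluded.
#' Undefined (NA) entries are dropped with a warning.
#'
#' @param ious numeric vector of per-class IOU fractions.
#' @return The mean IOU.
#' @examples
#' meanIoU(c(0.7186, 0.7727))   # 0.74565
#' @export
meanIoU <- function(ious) {
  if (!length(ious)) stop("meanIoU needs at least one IOU", call. = FALSE)
  if (anyNA(ious)) {
    warning("dropping undefined IOUs from the mean", call. = FALSE)
    ious <- ious[!is.na(ious)]
    if (!length(ious)) return(undefinedValue())
  }
  mean(ious)
}

#' Evaluate predictions over an image set
#'
#' Pools per-class confusion counts over all images (micro averaging), then
#' applies the metric formulas to the pooled counts. Duplicating every pair
#' leaves all metrics unchanged.
#'
#' @param preds,truths equal-length aligned lists of label masks.
#' @return List with `perClass` (data.frame: class, TP, FP, FN, P, R, F1,
#'   FIOU for grain and impurity) and `FMIOU`.
#' @export
evaluateSet <- function(preds, truths) {
  if (length(preds) != length(truths))
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 length(preds), length(truths)), call. = FALSE)
  if (!length(preds)) stop("empty evaluation set", call. = FALSE)
  rows <- lapply(c(grain = 1L, impurity = 2L), function(cl) {
    tp <- fp <- fn <- 0
    for (i in seq_along(preds)) {
      tab <- confusionTable(preds[[i]], truths[[i]], cl)
      tp <- tp + tab$TP; fp <- fp + tab$FP; fn <- fn + tab$FN
    }
    tab <- list(classId = cl, TP = tp, FP = fp, FN = fn)
    P <- pixelPrecision(tab); R <- pixelRecall(tab)
    data.frame(class = c("grain", "impurity")[cl], TP = tp, FP = fp, FN = fn,
               P = P, R = R, F1 = f1Score(P, R), FIOU = iouScore(tab))
  })
  perClass <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(perClass = perClass, FMIOU = meanIoU(perClass$FIOU))
}

#' Write an evaluation report
#'
#' Saves the per-class metrics plus MIOU (and optionally the mean inference
#' time) as CSV, and returns a pretty text table in the layout of the usual
#' per-backbone comparison tables.
#'
#' @param summary result of [evaluateSet()].
#' @param csvPath output CSV path (optional).
#' @param speedMs mean per-image milliseconds from [measureSpeed()] (optional).
#' @return Character vector of report lines, invisibly printed.
#' @export
metricsReport <- function(summary, csvPath = NULL, speedMs = NULL) {
  pc <- summary$perClass
  lines <- c(
    sprintf("%-10s %8s %8s %8s %8s", "class", "P(%)", "R(%)", "F1(%)", "IOU"),
    sprintf("%-10s %8.2f %8.2f %8.2f %8.4f",
            pc$class, 100 * pc$P, 100 * pc$R, 100 * pc$F1, pc$FIOU),
    sprintf("%-10s %35.4f", "MIOU", summary$FMIOU))
  if (!is.null(speedMs))
    lines <- c(lines, sprintf("%-10s %32.1f ms", "I_v", speedMs))
  if (!is.null(csvPath)) {
    out <- pc
    out$FMIOU <- summary$FMIOU
    if (!is.null(speedMs)) out$Iv_ms <- as.numeric(speedMs)
    write.csv(out, csvPath, row.names = FALSE)
  }
  invisible(lines)
}
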