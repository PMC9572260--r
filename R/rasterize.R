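## Polygon rasterisation to integer label masks.
##
## Coordinates are 0-based, x rightward, y downward; the centre of matrix cell
## (r, c) is (x, y) = (c - 0.5, r - 0.5). A pixel belongs to a polygon when
## its centre is inside under the even-odd rule, with half-open scanline
## intervals so shared edges never double-fill.

## Row/column indices of all pixels whose centres fall inside the polygon.
## pts: n x 2 matrix of (x, y) vertices. Returns linear indices into an
## H x W matrix (column-major), or integer(0).
polygonPixelIndices <- function(pts, width, height) {
  n <- nrow(pts)
  if (is.null(n) || n < 3L) return(integer(0))
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- pts[c(2:n, 1L), 1]; y2 <- pts[c(2:n, 1L), 2]
  keep <- y1 != y2                      # horizontal edges never cross a scanline
  if (!any(keep)) return(integer(0))
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  rlo <- max(1L, as.integer(ceiling(min(y1, y2) + 0.5)))
  rhi <- min(height, as.integer(floor(max(y1, y2) + 0.5)))
  if (rlo > rhi) return(integer(0))
  out <- vector("list", rhi - rlo + 1L)
  slope <- (x2 - x1) / (y2 - y1)
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  for (r in rlo:rhi) {
    yc <- r - 0.5
    hit <- ylo <= yc & yc < yhi         # half-open: counts each crossing once
    if (!any(hit)) next
    xc <- sort(x1[hit] + (yc - y1[hit]) * slope[hit])
    m <- length(xc)
    if (m %% 2L != 0L) next             # defensive; cannot happen for closed polygons
    cols <- integer(0)
    for (k in seq(1L, m, by = 2L)) {
      c0 <- as.integer(ceiling(xc[k] + 0.5))
      c1 <- as.integer(ceiling(xc[k + 1L] + 0.5)) - 1L
      c0 <- max(c0, 1L); c1 <- min(c1, width)
      if (c0 <= c1) cols <- c(cols, c0:c1)
    }
    if (length(cols)) out[[r - rlo + 1L]] <- r + (cols - 1L) * height
  }
  as.integer(unlist(out, use.names = FALSE))
}

## Signed polygon area (shoelace); zero flags a degenerate polygon.
polygonArea <- function(pts) {
  n <- nrow(pts)
  if (is.null(n) || n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y) / 2
}

#' Rasterise labelled polygons to a label mask
#'
#' Pixels whose centre lies inside a polygon (even-odd rule) receive the
#' polygon's class label; pixels inside no polygon stay background (0).
#' Overlaps are resolved by list order: a later polygon overwrites earlier
#' ones, mirroring the draw-order semantics of polygon annotation tools.
#' Degenerate (zero-area) polygons are skipped with a warning.
#'
#' @param annotations list of annotations as returned by [readLabelme()], or
#'   any list of lists with fields `label` (0, 1 or 2, or one of
#'   "background"/"grain"/"impurity") and `points` (n x 2 matrix of 0-based
#'   x,y vertices).
#' @param width,height output mask size in pixels.
#' @return Integer matrix `height` x `width` with values in \{0, 1, 2\}.
#' @examples
#' tri <- list(label = 1L, points = cbind(c(1, 30, 1), c(1, 1, 30)))
#' m <- rasterizeAnnotations(list(tri), width = 32, height = 32)
#' table(m)
#' @export
rasterizeAnnotations <- function(annotations, width, height) {
  width <- assertCount(width, "width"); height <- assertCount(height, "height")
  if (width < 1L || height < 1L) stop("mask dimensions must be positive")
  mask <- matrix(0L, nrow = height, ncol = width)
  for (ann in annotations) {
    lab <- annotationLabel(ann$label)
    pts <- as.matrix(ann$points)
    if (abs(polygonArea(pts)) == 0) {
      warning("skipping degenerate (zero-area) polygon", call. = FALSE)
      next
    }
    idx <- polygonPixelIndices(pts, width, height)
    if (length(idx)) mask[idx] <- lab
  }
  mask
}

## Accept numeric labels 0/1/2 or the canonical label strings.
annotationLabel <- function(label) {
  if (is.numeric(label)) {
    if (!label %in% 0:2)
      stop(sprintf("unknown numeric label %s (expected 0, 1 or 2)", label),
           call. = FALSE)
    return(as.integer(label))
  }
  lut <- c(background = 0L, grain = 1L, impurity = 2L)
  if (!label %in% names(lut))
    stop(sprintf("unknown label string '%s' (expected background/grain/impurity)",
                 label), call. = FALSE)
  lut[[label]]
}
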