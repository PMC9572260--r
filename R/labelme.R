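## LabelMe-style JSON annotations and PNG image/mask I/O.

labelNames <- c("background", "grain", "impurity")

#' Read a LabelMe-style annotation file
#'
#' Parses the polygon shapes of a LabelMe JSON file into the package's
#' annotation list form. Only polygon shapes are supported; labels must be
#' one of `background`, `grain`, `impurity` (or the numeric strings 0/1/2).
#'
#' @param jsonPath path to the JSON file.
#' @return List of annotations, each a list with `label` (integer 0/1/2),
#'   `labelName`, `points` (n x 2 matrix of 0-based x,y vertices) and
#'   `sourceImage`. Attributes `imageWidth`/`imageHeight` carry the canvas
#'   size when present in the file.
#' @export
readLabelme <- function(jsonPath) {
  if (!file.exists(jsonPath))
    stop(sprintf("annotation file '%s' does not exist", jsonPath), call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(jsonPath, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("cannot parse '%s' as LabelMe JSON: %s",
                                 jsonPath, conditionMessage(e)), call. = FALSE))
  shapes <- doc$shapes
  anns <- lapply(shapes, function(sh) {
    if (!is.null(sh$shape_type) && !identical(sh$shape_type, "polygon"))
      stop(sprintf("unsupported shape_type '%s' in '%s' (only polygons)",
                   sh$shape_type, jsonPath), call. = FALSE)
    labName <- sh$label
    lab <- if (grepl("^[0-9]+$", labName)) annotationLabel(as.numeric(labName))
           else annotationLabel(labName)
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(p)))
    if (is.null(pts) || nrow(pts) < 3L)
      stop(sprintf("polygon with fewer than 3 vertices in '%s'", jsonPath),
           call. = FALSE)
    list(label = lab, labelName = labelNames[lab + 1L], points = pts,
         sourceImage = if (is.null(doc$imagePath)) NA_character_ else doc$imagePath)
  })
  attr(anns, "imageWidth") <- doc$imageWidth
  attr(anns, "imageHeight") <- doc$imageHeight
  anns
}

#' Write polygons as a LabelMe-style annotation file
#'
#' @param polygons list of lists with `label` ("grain"/"impurity"/"background"
#'   or 0/1/2) and `points` (n x 2 matrix of 0-based x,y vertices).
#' @param jsonPath output path.
#' @param imagePath image file name stored in the annotation.
#' @param width,height canvas size in pixels.
#' @return Invisibly, `jsonPath`.
#' @export
writeLabelme <- function(polygons, jsonPath, imagePath = "", width, height) {
  shapes <- lapply(polygons, function(p) {
    lab <- annotationLabel(p$label)
    pts <- as.matrix(p$points)
    list(label = labelNames[lab + 1L],
         points = lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
         group_id = NULL, shape_type = "polygon", flags = setNames(list(), character(0)))
  })
  doc <- list(version = "5.0.1", flags = setNames(list(), character(0)),
              shapes = shapes, imagePath = imagePath, imageData = NULL,
              imageHeight = as.integer(height), imageWidth = as.integer(width))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE), jsonPath)
  invisible(jsonPath)
}

#' Read and write RGB images and label masks as PNG
#'
#' Images are stored as ordinary RGB PNGs; masks as single-channel PNGs whose
#' 8-bit pixel values are literally 0, 1 and 2.
#'
#' @param path file path.
#' @param image numeric array [H, W, 3] with values in [0, 1].
#' @param mask integer matrix with values 0/1/2.
#' @return Readers return the array/matrix; writers return the path invisibly.
#' @name pngIO
NULL

#' @rdname pngIO
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname pngIO
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a
}

#' @rdname pngIO
#' @export
writeMaskPNG <- function(mask, path) {
  assertMask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname pngIO
#' @export
readMaskPNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- matrix(as.integer(round(a * 255)), nrow = nrow(a))
  assertMask(m, path)
  m
}
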