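## Dataset preparation: bilinear/nearest resizing, the six-fold geometric
## augmentation, and the random train/validation/test split.

## Resize [H, W] or [H, W, C] arrays. EBImage's first dimension corresponds to
## our row (H) dimension; extra dimensions are resized per-plane.
resizeArray <- function(a, height, width, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  if (height < 1L || width < 1L)
    stop("target dimensions must be positive", call. = FALSE)
  out <- EBImage::resize(EBImage::Image(a), w = height, h = width, filter = filter)
  out <- as.numeric(out)
  if (length(dim(a)) == 3L) array(out, dim = c(height, width, dim(a)[3]))
  else matrix(out, nrow = height, ncol = width)
}

#' Resize an aligned image/mask pair
#'
#' The RGB image is resampled with bilinear interpolation (the protocol used
#' to bring 1280 x 1024 camera frames to the model's 512 x 512 input); the
#' label mask is resampled with nearest-neighbour so labels remain in
#' \{0, 1, 2\} (bilinear interpolation of labels would invent invalid classes).
#'
#' @param image numeric array [H, W, 3].
#' @param mask integer matrix [H, W] over \{0,1,2\}, or NULL.
#' @param height,width target size in pixels (default 512 x 512).
#' @return List with elements `image` and `mask` at the target size.
#' @export
resizePair <- function(image, mask = NULL, height = 512L, width = 512L) {
  height <- assertCount(height, "height"); width <- assertCount(width, "width")
  if (height < 1L || width < 1L)
    stop("target size must be positive", call. = FALSE)
  img2 <- if (identical(dim(image)[1:2], c(height, width))) image
          else resizeArray(image, height, width, "bilinear")
  msk2 <- NULL
  if (!is.null(mask)) {
    assertMask(mask)
    msk2 <- if (identical(dim(mask), c(height, width))) mask
            else {
              m <- resizeArray(mask, height, width, "none")
              matrix(as.integer(round(m)), nrow = height)
            }
  }
  list(image = img2, mask = msk2)
}

rotateCCW <- function(m) t(m)[ncol(m):1, , drop = FALSE]

applyPlanes <- function(a, f) {
  if (length(dim(a)) == 2L) return(f(a))
  planes <- lapply(seq_len(dim(a)[3]), function(ch) f(a[, , ch]))
  array(unlist(planes, use.names = FALSE),
        dim = c(dim(planes[[1]]), dim(a)[3]))
}

## Scale by `factor` then restore the original canvas: zoom-out variants are
## centre-padded with background (zeros), zoom-in variants centre-cropped.
scaleToCanvas <- function(a, factor, filter) {
  d <- dim(a)[1:2]
  hs <- max(1L, as.integer(round(d[1] * factor)))
  ws <- max(1L, as.integer(round(d[2] * factor)))
  s <- resizeArray(a, hs, ws, filter)
  if (length(dim(a)) == 2L) dim(s) <- c(hs, ws, 1L) else dim(s) <- c(hs, ws, dim(a)[3])
  out <- array(0, dim = c(d, dim(s)[3]))
  if (factor <= 1) {
    r0 <- (d[1] - hs) %/% 2L; c0 <- (d[2] - ws) %/% 2L
    out[r0 + seq_len(hs), c0 + seq_len(ws), ] <- s
  } else {
    r0 <- (hs - d[1]) %/% 2L; c0 <- (ws - d[2]) %/% 2L
    out <- s[r0 + seq_len(d[1]), c0 + seq_len(d[2]), , drop = FALSE]
  }
  if (length(dim(a)) == 2L) matrix(out, nrow = d[1]) else out
}

#' Six-fold geometric augmentation of an image/mask pair
#'
#' Produces the six deterministic variants of the training protocol: 90 and
#' 270 degree counterclockwise rotation, 0.6x and 1.8x rescaling (restored to
#' the original canvas by centre background-padding / centre-cropping), and
#' horizontal and vertical mirroring. The identical geometric transform is
#' applied to the mask, using nearest-neighbour resampling where interpolation
#' is involved. Together with the original, one pair yields 7 training pairs
#' (350 originals become 2450).
#'
#' @param image numeric array [H, W, 3].
#' @param mask integer matrix [H, W] over \{0,1,2\} (optional).
#' @return Named list of six lists, each with `image` and `mask`:
#'   `rot90`, `rot270`, `scale0.6`, `scale1.8`, `mirrorH`, `mirrorV`.
#' @export
augmentPair <- function(image, mask = NULL) {
  if (!is.null(mask)) {
    assertMask(mask)
    stopifnot(identical(dim(image)[1:2], dim(mask)))
  }
  both <- function(fImg, fMask = fImg) {
    list(image = applyPlanes(image, fImg),
         mask = if (is.null(mask)) NULL else {
           m <- applyPlanes(mask, fMask)
           matrix(as.integer(round(m)), nrow = nrow(m))
         })
  }
  list(
    rot90      = both(rotateCCW),
    rot270     = both(function(m) rotateCCW(rotateCCW(rotateCCW(m)))),
    `scale0.6` = list(image = scaleToCanvas(image, 0.6, "bilinear"),
                      mask = if (is.null(mask)) NULL else
                        matrix(as.integer(round(scaleToCanvas(mask, 0.6, "none"))),
                               nrow = nrow(mask))),
    `scale1.8` = list(image = scaleToCanvas(image, 1.8, "bilinear"),
                      mask = if (is.null(mask)) NULL else
                        matrix(as.integer(round(scaleToCanvas(mask, 1.8, "none"))),
                               nrow = nrow(mask))),
    mirrorH    = both(function(m) m[, ncol(m):1, drop = FALSE]),
    mirrorV    = both(function(m) m[nrow(m):1, , drop = FALSE])
  )
}

#' Augment a whole set of pairs
#'
#' @param pairs list of lists with `image` and `mask`.
#' @return List of length `7 * length(pairs)`: every original followed by its
#'   six variants.
#' @export
augmentSet <- function(pairs) {
  out <- vector("list", 7L * length(pairs))
  j <- 0L
  for (p in pairs) {
    out[[j + 1L]] <- p
    vars <- augmentPair(p$image, p$mask)
    for (v in vars) { j <- j + 1L; out[[j + 1L]] <- v }
    j <- j + 1L
  }
  out
}

#' Random train/validation/test split
#'
#' Uniform random disjoint assignment of files to the three sets, reproducible
#' under `seed`. The default counts follow the 350/50/100 protocol (the test
#' set is never augmented downstream).
#'
#' @param files character vector of file identifiers.
#' @param counts integer vector `c(train, val, test)`.
#' @param seed integer seed.
#' @return List with elements `train`, `val`, `test` (disjoint character
#'   vectors of the requested sizes) and `seed`.
#' @export
splitDataset <- function(files, counts = c(350L, 50L, 100L), seed = 1L) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  counts <- as.integer(counts)
  if (length(files) < sum(counts))
    stop(sprintf("need at least %d files for a %d/%d/%d split, got %d",
                 sum(counts), counts[1], counts[2], counts[3], length(files)),
         call. = FALSE)
  withSeed(seed, {
    perm <- sample(files, sum(counts))
    list(train = perm[seq_len(counts[1])],
         val   = perm[counts[1] + seq_len(counts[2])],
         test  = perm[counts[1] + counts[2] + seq_len(counts[3])],
         seed  = as.integer(seed))
  })
}

#' Load image/mask pairs written by makeDataset
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @param images optional subset of image file names (e.g. one side of a
#'   [splitDataset()] result).
#' @param height,width optional target size; pairs are passed through
#'   [resizePair()] when given.
#' @return List of lists with `image`, `mask` and `name`.
#' @export
loadDataset <- function(dir, images = NULL, height = NULL, width = NULL) {
  manifestPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manifestPath))
    stop(sprintf("no manifest.csv in '%s'", dir), call. = FALSE)
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  if (!is.null(images)) man <- man[man$image %in% images, , drop = FALSE]
  lapply(seq_len(nrow(man)), function(i) {
    img <- readImagePNG(file.path(dir, man$image[i]))
    msk <- readMaskPNG(file.path(dir, man$mask[i]))
    if (!is.null(height)) {
      rp <- resizePair(img, msk, height, width)
      img <- rp$image; msk <- rp$mask
    }
    list(image = img, mask = msk, name = man$image[i])
  })
}
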