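## Synthetic grain-pile scenes with exact ground truth.
##
## Grains are drawn as filled ellipse polygons, impurities as bent straw
## strips or thin husk arcs, all on a dark bin background. Objects are
## rasterised in draw order (later object wins at overlaps), so the returned
## polygons re-rasterise to the returned mask exactly; blur and sensor noise
## are applied to the image only, never to the mask.

## Regular polygon approximation of a rotated ellipse.
ellipsePolygon <- function(cx, cy, a, b, theta, nVertices = 24L) {
  t <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(theta) - y * sin(theta),
        cy + x * sin(theta) + y * cos(theta))
}

## Bent strip: a 4-point polyline with small heading changes, offset
## perpendicular by +/- width/2 to make a thin closed polygon (straw).
strawPolygon <- function(cx, cy, len, wid, theta0) {
  nSeg <- 3L
  seg <- len / nSeg
  ang <- theta0 + cumsum(c(0, rnorm(nSeg, sd = 0.35)))
  dx <- c(0, cumsum(seg * cos(ang))); dy <- c(0, cumsum(seg * sin(ang)))
  px <- cx + dx - mean(dx); py <- cy + dy - mean(dy)
  # perpendicular of each vertex: average of adjacent segment normals
  segAng <- atan2(diff(py), diff(px))
  vAng <- c(segAng[1], (segAng[-1] + segAng[-nSeg]) / 2, segAng[nSeg])
  nx <- -sin(vAng) * wid / 2; ny <- cos(vAng) * wid / 2
  rbind(cbind(px + nx, py + ny), cbind(rev(px - nx), rev(py - ny)))
}

## Thin partial annulus (husk): arc at radius r with radial thickness wid.
huskPolygon <- function(cx, cy, r, wid, theta0, arc = pi * 0.8, nArc = 12L) {
  t <- seq(theta0, theta0 + arc, length.out = nArc)
  rbind(cbind(cx + (r + wid / 2) * cos(t), cy + (r + wid / 2) * sin(t)),
        cbind(cx + (r - wid / 2) * cos(rev(t)), cy + (r - wid / 2) * sin(rev(t))))
}

runifRange <- function(n, range) runif(n, range[1], range[2])

#' Render a synthetic grain-pile scene
#'
#' Draws `nGrains` filled grain ellipses and then `nImpurities` elongated
#' straw/husk fragments on the background, in draw order (later object
#' overwrites earlier ones where they overlap). Per-object colour jitter,
#' Gaussian blur and additive sensor noise are applied to the image; the
#' label mask and the outline polygons are exact and mutually consistent:
#' `rasterizeAnnotations(polygonsOf(x), W, H)` reproduces `maskOf(x)`.
#'
#' @param spec a [SceneSpec()].
#' @return A [RenderedSample-class] with aligned image, mask, true pixel
#'   counts and labelled polygons.
#' @examples
#' s <- renderScene(SceneSpec(width = 96, height = 96, nGrains = 30,
#'                            nImpurities = 2, seed = 7))
#' trueCounts(s)
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  W <- spec@width; H <- spec@height
  withSeed(spec@seed, {
    polys <- vector("list", spec@nGrains + spec@nImpurities)
    k <- 0L
    if (spec@nGrains > 0L) for (i in seq_len(spec@nGrains)) {
      a <- runifRange(1, spec@grainAxisRange)
      b <- runifRange(1, spec@grainAxisRange * c(0.55, 0.8))
      m <- max(a, b) + 1
      if (2 * m >= min(W, H))
        stop("grain axes too large for the canvas", call. = FALSE)
      pts <- ellipsePolygon(runif(1, m, W - m), runif(1, m, H - m),
                            a, b, runif(1, 0, pi))
      k <- k + 1L; polys[[k]] <- list(label = "grain", points = pts)
    }
    if (spec@nImpurities > 0L) for (i in seq_len(spec@nImpurities)) {
      len <- runifRange(1, spec@impurityLengthRange)
      wid <- runifRange(1, spec@impurityWidthRange)
      if (len >= min(W, H))
        stop("impurity length too large for the canvas", call. = FALSE)
      m <- len / 2 + wid + 1
      cx <- runif(1, m, W - m); cy <- runif(1, m, H - m)
      pts <- if (runif(1) < 0.7)
        strawPolygon(cx, cy, len, wid, runif(1, 0, pi))
      else
        huskPolygon(cx, cy, len / 2, wid, runif(1, 0, 2 * pi))
      k <- k + 1L; polys[[k]] <- list(label = "impurity", points = pts)
    }
    polys <- polys[seq_len(k)]

    ## paint object indices in draw order, then derive mask and image
    objIdx <- matrix(0L, nrow = H, ncol = W)
    for (j in seq_along(polys)) {
      idx <- polygonPixelIndices(polys[[j]]$points, W, H)
      if (length(idx)) objIdx[idx] <- j
    }
    labels <- vapply(polys, function(p) annotationLabel(p$label), integer(1))
    mask <- matrix(0L, nrow = H, ncol = W)
    vis <- objIdx > 0L
    mask[vis] <- labels[objIdx[vis]]

    base <- list(spec@grainColor, spec@impurityColor)
    img <- array(rep(spec@backgroundColor, each = H * W), dim = c(H, W, 3))
    if (k > 0L) {
      cols <- t(vapply(seq_len(k), function(j) {
        pmin(pmax(base[[labels[j]]] + rnorm(3, sd = spec@colorJitterSd), 0), 1)
      }, numeric(3)))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[vis] <- cols[objIdx[vis], ch]
        img[, , ch] <- plane
      }
    }
    if (spec@blurSigma > 0)
      img <- as.numeric(EBImage::gblur(EBImage::Image(img), sigma = spec@blurSigma)) |>
        array(dim = c(H, W, 3))
    if (spec@noiseSd > 0)
      img <- img + array(rnorm(H * W * 3, sd = spec@noiseSd), dim = c(H, W, 3))
    img <- pmin(pmax(img, 0), 1)

    new("RenderedSample", image = img, mask = mask,
        trueCounts = c(Tw = sum(mask == 1L), Tz = sum(mask == 2L)),
        polygons = polys)
  })
}

#' Simulate weighed masses for a rendered sample
#'
#' Emulates the manual reference measurement: the whole sample (grain +
#' impurity) and the separated impurity fraction are weighed. Masses follow
#' the per-1000-pixel densities of the [MassModel()], each perturbed by
#' independent multiplicative Gaussian noise with coefficient of variation
#' `noiseCv` (clamped at zero mass).
#'
#' @param counts named vector with elements `Tw` (grain pixels) and `Tz`
#'   (impurity pixels), e.g. from [trueCounts()].
#' @param model a [MassModel()].
#' @param seed integer seed for the weighing noise.
#' @return Named numeric vector `c(w = sample mass, wz = impurity mass)` in
#'   grams, with `0 <= wz <= w`.
#' @export
sampleMasses <- function(counts, model, seed = 1L) {
  stopifnot(is(model, "MassModel"))
  validObject(model)
  tw <- assertCount(counts[["Tw"]], "Tw"); tz <- assertCount(counts[["Tz"]], "Tz")
  withSeed(seed, {
    fac <- pmax(1 + rnorm(2, sd = model@noiseCv), 0)
    wz <- model@impurityMassPerKpx * tz / 1000 * fac[1]
    wg <- model@grainMassPerKpx * tw / 1000 * fac[2]
    c(w = wz + wg, wz = wz)
  })
}

#' Write a synthetic dataset to disk
#'
#' Renders `nImages` scenes (object counts jittered by +/-20% around the SceneSpec
#' so the set has variety) and writes, per image, an RGB PNG, a single-channel
#' label-mask PNG with literal pixel values 0/1/2, and a LabelMe-style JSON
#' annotation, plus a `manifest.csv` listing the files and true pixel counts.
#'
#' @param spec a [SceneSpec()]; its seed is ignored in favour of `seed`.
#' @param nImages number of scenes to render.
#' @param outDir output directory (created if missing).
#' @param seed integer seed; each image derives a child seed from it.
#' @return Invisibly, the manifest data frame (image, mask, json, Tw, Tz).
#' @export
makeDataset <- function(spec, nImages, outDir, seed = 1L) {
  stopifnot(is(spec, "SceneSpec"))
  nImages <- assertCount(nImages, "nImages")
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", outDir), call. = FALSE)
  rows <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    si <- childSeed(seed, i)
    counts <- withSeed(childSeed(si, 1L), {
      c(round(spec@nGrains * runif(1, 0.8, 1.2)),
        round(spec@nImpurities * runif(1, 0.8, 1.2)))
    })
    ispec <- spec
    ispec@nGrains <- as.integer(counts[1]); ispec@nImpurities <- as.integer(counts[2])
    ispec@seed <- childSeed(si, 2L)
    s <- renderScene(ispec)
    stem <- sprintf("scene_%04d", i)
    imgPath <- file.path(outDir, paste0(stem, ".png"))
    maskPath <- file.path(outDir, paste0(stem, "_mask.png"))
    jsonPath <- file.path(outDir, paste0(stem, ".json"))
    writeImagePNG(imageOf(s), imgPath)
    writeMaskPNG(maskOf(s), maskPath)
    writeLabelme(polygonsOf(s), jsonPath, imagePath = basename(imgPath),
                 width = spec@width, height = spec@height)
    tc <- trueCounts(s)
    rows[[i]] <- data.frame(image = basename(imgPath), mask = basename(maskPath),
                            json = basename(jsonPath),
                            Tw = tc[["Tw"]], Tz = tc[["Tz"]])
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
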