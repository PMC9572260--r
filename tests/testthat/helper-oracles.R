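# Independent brute-force oracles, deliberately written as plain per-pixel
# loops so they share no code path with the implementations they check.

# Even-odd point-in-polygon by ray casting from each pixel centre.
bruteForceRasterize <- function(annotations, width, height) {
  inside <- function(px, py, pts) {
    n <- nrow(pts)
    crossings <- 0L
    for (e in seq_len(n)) {
      x1 <- pts[e, 1]; y1 <- pts[e, 2]
      x2 <- pts[e %% n + 1L, 1]; y2 <- pts[e %% n + 1L, 2]
      if ((y1 > py) != (y2 > py)) {
        xc <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        if (xc > px) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }
  labOf <- function(lab) {
    if (is.numeric(lab)) as.integer(lab)
    else c(background = 0L, grain = 1L, impurity = 2L)[[lab]]
  }
  mask <- matrix(0L, nrow = height, ncol = width)
  for (ann in annotations) {
    pts <- as.matrix(ann$points)
    for (r in seq_len(height)) for (c in seq_len(width)) {
      if (inside(c - 0.5, r - 0.5, pts)) mask[r, c] <- labOf(ann$label)
    }
  }
  mask
}

# Per-pixel recount of TP/FP/FN and the five metrics, by explicit loops.
bruteForceMetrics <- function(pred, truth) {
  perClass <- list()
  for (cl in 1:2) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(pred)) {
      p <- pred[i]; t <- truth[i]
      if (p == cl && t == cl) tp <- tp + 1L
      if (p == cl && t != cl) fp <- fp + 1L
      if (p != cl && t == cl) fn <- fn + 1L
    }
    P <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    R <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    F1 <- if (!is.na(P) && !is.na(R) && P + R > 0) 2 * P * R / (P + R) else NA_real_
    IOU <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
    perClass[[cl]] <- c(TP = tp, FP = fp, FN = fn, P = P, R = R, F1 = F1, IOU = IOU)
  }
  ious <- c(perClass[[1]][["IOU"]], perClass[[2]][["IOU"]])
  list(grain = perClass[[1]], impurity = perClass[[2]],
       MIOU = mean(ious[!is.na(ious)]))
}

# Small random label masks for property tests.
randomMask <- function(h, w) matrix(sample(0:2, h * w, replace = TRUE), h, w)

# Scene used by desk-scale model tests: few, large, crisp objects.
overfitScene <- function(seed) {
  renderScene(SceneSpec(64, 64, nGrains = 30L, nImpurities = 3L,
                        grainAxisRange = c(3, 6),
                        impurityLengthRange = c(12, 26),
                        impurityWidthRange = c(2.5, 4.5),
                        blurSigma = 0, noiseSd = 0.01, seed = seed))
}

scenePair <- function(spec) {
  s <- renderScene(spec)
  list(image = imageOf(s), mask = maskOf(s))
}

# 128 x 128 "cropped field of view" scene: per-object pixel statistics match
# the 512 x 512 working resolution, with proportionally fewer objects.
cropSceneSpec <- function(seed) {
  SceneSpec(width = 128L, height = 128L, nGrains = 56L, nImpurities = 2L,
            grainAxisRange = c(5, 11), impurityLengthRange = c(30, 80),
            impurityWidthRange = c(4, 9), seed = seed)
}
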