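## Backbone feature extractors for the DeepLabV3+ encoder.
##
## Each backbone is declared as a DAG on the shared engine and reports its
## encoder output (at the configured output stride, final stage atrous) and
## its low-level feature tap (output stride 4) for the decoder skip.
## `widthMultiplier` scales every channel count, allowing desk-scale models.

scaledCh <- function(n, wm) max(4L, as.integer(round(n * wm)))

## conv -> instance norm -> activation
cbr <- function(G, inId, cin, cout, k, stride = 1L, dilation = 1L,
                act = "relu") {
  c1 <- addNode(G, "conv", inId, convModule(cin, cout, k, stride, dilation))
  n1 <- addNode(G, "norm", c1, normModule(cout))
  if (is.null(act)) n1 else addNode(G, act, n1)
}

## depthwise-separable conv: dw3x3 -> norm -> pw1x1 -> norm -> relu
sepConv <- function(G, inId, cin, cout, stride = 1L, dilation = 1L) {
  d1 <- addNode(G, "dwconv", inId, dwConvModule(cin, 3L, stride, dilation))
  n1 <- addNode(G, "norm", d1, normModule(cin))
  c1 <- addNode(G, "conv", n1, convModule(cin, cout, 1L))
  n2 <- addNode(G, "norm", c1, normModule(cout))
  addNode(G, "relu", n2)
}

backboneTiny <- function(G, inId, wm, outputStride) {
  c1 <- scaledCh(16, wm); c2 <- scaledCh(24, wm)
  c3 <- scaledCh(32, wm); c4 <- scaledCh(48, wm)
  s1 <- cbr(G, inId, 3L, c1, 3L, 2L)                      # os 2
  low <- cbr(G, s1, c1, c2, 3L, 2L)                       # os 4
  s3 <- cbr(G, low, c2, c3, 3L, 2L)                       # os 8
  if (outputStride == 16L) {
    s4 <- cbr(G, s3, c3, c4, 3L, 2L)                      # os 16
    enc <- cbr(G, s4, c4, c4, 3L, 1L, 2L)                 # atrous final stage
  } else {
    s4 <- cbr(G, s3, c3, c4, 3L, 1L, 2L)
    enc <- cbr(G, s4, c4, c4, 3L, 1L, 2L)
  }
  list(encId = enc, encCh = c4, lowId = low, lowCh = c2)
}

## MobileNetV2 inverted residual block
invResidual <- function(G, inId, cin, cout, expand, stride, dilation) {
  mid <- cin * expand
  h <- inId; hc <- cin
  if (expand != 1L) {
    h <- cbr(G, h, cin, mid, 1L, act = "relu6")
    hc <- mid
  }
  d1 <- addNode(G, "dwconv", h, dwConvModule(hc, 3L, stride, dilation))
  n1 <- addNode(G, "norm", d1, normModule(hc))
  a1 <- addNode(G, "relu6", n1)
  p1 <- addNode(G, "conv", a1, convModule(hc, cout, 1L))
  n2 <- addNode(G, "norm", p1, normModule(cout))
  if (stride == 1L && cin == cout) addNode(G, "add", c(n2, inId)) else n2
}

backboneMobileNetV2 <- function(G, inId, wm, outputStride) {
  stages <- list(  # (expand, channels, repeats, stride)
    c(1L, 16L, 1L, 1L), c(6L, 24L, 2L, 2L), c(6L, 32L, 3L, 2L),
    c(6L, 64L, 4L, 2L), c(6L, 96L, 3L, 1L), c(6L, 160L, 3L, 2L),
    c(6L, 320L, 1L, 1L))
  cur <- cbr(G, inId, 3L, scaledCh(32, wm), 3L, 2L, act = "relu6")
  curCh <- scaledCh(32, wm); os <- 2L; dil <- 1L
  lowId <- NULL; lowCh <- NULL
  for (stg in stages) {
    expand <- stg[1]; cout <- scaledCh(stg[2], wm); reps <- stg[3]; s <- stg[4]
    for (r in seq_len(reps)) {
      stride <- if (r == 1L) s else 1L
      if (stride > 1L && os >= outputStride) { stride <- 1L; dil <- 2L }
      cur <- invResidual(G, cur, curCh, cout, expand, stride, dil)
      curCh <- cout
      if (stride > 1L) os <- os * 2L
    }
    if (stg[2] == 24L) { lowId <- cur; lowCh <- curCh }   # os 4 tap
  }
  list(encId = cur, encCh = curCh, lowId = lowId, lowCh = lowCh)
}

## ResNet bottleneck block (1x1 reduce, 3x3, 1x1 expand, residual)
bottleneck <- function(G, inId, cin, mid, cout, stride, dilation) {
  a <- cbr(G, inId, cin, mid, 1L)
  b <- cbr(G, a, mid, mid, 3L, stride, dilation)
  c1 <- cbr(G, b, mid, cout, 1L, act = NULL)
  sc <- if (stride != 1L || cin != cout)
    cbr(G, inId, cin, cout, 1L, stride, act = NULL) else inId
  addNode(G, "relu", addNode(G, "add", c(c1, sc)))
}

backboneResNet <- function(G, inId, wm, outputStride, layers) {
  stem <- cbr(G, inId, 3L, scaledCh(64, wm), 7L, 2L)       # os 2
  pool <- addNode(G, "maxpool", stem)                      # os 4
  cur <- pool; curCh <- scaledCh(64, wm)
  stageMid <- c(64L, 128L, 256L, 512L)
  stageStride <- c(1L, 2L, 2L, 2L)
  os <- 4L; dil <- 1L
  lowId <- NULL; lowCh <- NULL
  for (st in 1:4) {
    mid <- scaledCh(stageMid[st], wm); cout <- mid * 4L
    for (r in seq_len(layers[st])) {
      stride <- if (r == 1L) stageStride[st] else 1L
      if (stride > 1L && os >= outputStride) { stride <- 1L; dil <- dil * 2L }
      cur <- bottleneck(G, cur, curCh, mid, cout, stride, dil)
      curCh <- cout
      if (stride > 1L) os <- os * 2L
    }
    if (st == 1L) { lowId <- cur; lowCh <- curCh }         # os 4 tap, 256 ch
  }
  list(encId = cur, encCh = curCh, lowId = lowId, lowCh = lowCh)
}

## Xception-style block of three separable convs with residual shortcut
xceptionBlock <- function(G, inId, cin, couts, stride, dilation) {
  h <- sepConv(G, inId, cin, couts[1], 1L, dilation)
  h <- sepConv(G, h, couts[1], couts[2], 1L, dilation)
  h <- sepConv(G, h, couts[2], couts[3], stride, dilation)
  sc <- if (stride != 1L || cin != couts[3])
    cbr(G, inId, cin, couts[3], 1L, stride, act = NULL) else inId
  addNode(G, "add", c(h, sc))
}

backboneXception <- function(G, inId, wm, outputStride) {
  ch <- function(n) scaledCh(n, wm)
  e1 <- cbr(G, inId, 3L, ch(32), 3L, 2L)                   # os 2
  e2 <- cbr(G, e1, ch(32), ch(64), 3L, 1L)
  b1 <- xceptionBlock(G, e2, ch(64), rep(ch(128), 3), 2L, 1L)   # os 4
  low <- b1; lowCh <- ch(128)
  b2 <- xceptionBlock(G, b1, ch(128), rep(ch(256), 3), 2L, 1L)  # os 8
  if (outputStride == 16L) {
    b3 <- xceptionBlock(G, b2, ch(256), rep(ch(728), 3), 2L, 1L)  # os 16
    dil <- 2L
  } else {
    b3 <- xceptionBlock(G, b2, ch(256), rep(ch(728), 3), 1L, 2L)
    dil <- 4L
  }
  cur <- b3
  for (i in 1:16)                                          # middle flow
    cur <- xceptionBlock(G, cur, ch(728), rep(ch(728), 3), 1L,
                         if (outputStride == 16L) 1L else 2L)
  ex <- xceptionBlock(G, cur, ch(728), c(ch(728), ch(1024), ch(1024)), 1L, dil)
  ex <- sepConv(G, ex, ch(1024), ch(1536), 1L, dil)
  enc <- sepConv(G, ex, ch(1536), ch(2048), 1L, dil)
  list(encId = enc, encCh = ch(2048), lowId = low, lowCh = lowCh)
}

buildBackbone <- function(G, inId, backbone, wm, outputStride) {
  switch(backbone,
    tiny        = backboneTiny(G, inId, wm, outputStride),
    mobilenetv2 = backboneMobileNetV2(G, inId, wm, outputStride),
    resnet50    = backboneResNet(G, inId, wm, outputStride, c(3L, 4L, 6L, 3L)),
    resnet101   = backboneResNet(G, inId, wm, outputStride, c(3L, 4L, 23L, 3L)),
    xception65  = backboneXception(G, inId, wm, outputStride),
    stop(sprintf("unknown backbone '%s' (expected tiny, mobilenetv2, resnet50, resnet101 or xception65)",
                 backbone), call. = FALSE)
  )
}
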