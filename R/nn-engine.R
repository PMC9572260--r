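## Lightweight CPU engine for convolutional encoder-decoder networks.
##
## Feature maps are lists t(x = (H*W) x C matrix, H, W), pixels column-major
## over (row, col). Convolutions are computed as a sum of k^2 shifted
## pointwise matrix products ("shift-matmul"), which maps dilation and stride
## onto precomputed index tables and leaves the heavy lifting to BLAS.
## Networks are small DAGs of nodes evaluated in insertion order; the
## backward pass walks the tape in reverse, accumulating gradients per node.

.geomCache <- new.env(parent = emptyenv())

tensor <- function(x, H, W) list(x = x, H = H, W = W)

## ---- geometry -------------------------------------------------------------

## Index table for a k x k convolution: idx[p, o] is the row of the padded
## input (pad row = H*W + 1, reads as zero) feeding output pixel p through
## kernel offset o. "Same" padding, ceil-mode output size for stride > 1.
convGeom <- function(H, W, k, stride, dilation) {
  key <- sprintf("c%d_%d_%d_%d_%d", H, W, k, stride, dilation)
  g <- .geomCache[[key]]
  if (!is.null(g)) return(g)
  Hout <- as.integer(ceiling(H / stride)); Wout <- as.integer(ceiling(W / stride))
  h <- (k - 1L) %/% 2L
  ro <- rep(seq_len(Hout), Wout); co <- rep(seq_len(Wout), each = Hout)
  ri <- (ro - 1L) * stride + 1L; ci <- (co - 1L) * stride + 1L
  off <- expand.grid(dy = (-h:h) * dilation, dx = (-h:h) * dilation)
  n <- Hout * Wout
  idx <- matrix(0L, nrow = n, ncol = k * k)
  pad <- H * W + 1L
  for (o in seq_len(k * k)) {
    rr <- ri + off$dy[o]; cc <- ci + off$dx[o]
    inside <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx[, o] <- ifelse(inside, rr + (cc - 1L) * H, pad)
  }
  g <- list(idx = idx, Hout = Hout, Wout = Wout, pad = pad)
  .geomCache[[key]] <- g
  g
}

## Dense 1-D bilinear interpolation matrix (half-pixel centres), nOut x nIn.
interpMatrix <- function(nIn, nOut) {
  key <- sprintf("i%d_%d", nIn, nOut)
  m <- .geomCache[[key]]
  if (!is.null(m)) return(m)
  pos <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  lo <- pmin(pmax(floor(pos), 0), nIn - 1)
  hi <- pmin(lo + 1, nIn - 1)
  wHi <- pos - lo
  wHi[hi == lo] <- 0
  m <- matrix(0, nOut, nIn)
  m[cbind(seq_len(nOut), lo + 1)] <- 1 - wHi
  m[cbind(seq_len(nOut), hi + 1)] <- m[cbind(seq_len(nOut), hi + 1)] + wHi
  .geomCache[[key]] <- m
  m
}

## ---- parameters and optimiser ---------------------------------------------

newParam <- function(value) {
  e <- new.env(parent = emptyenv())
  e$w <- value
  e$g <- array(0, dim = dim(value) %||% length(value))
  e$m <- e$g; e$v <- e$g
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zeroGrads <- function(params) for (p in params) p$g[] <- 0

adamStep <- function(params, lr, step, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0) {
  for (p in params) {
    g <- p$g
    if (weightDecay > 0) g <- g + weightDecay * p$w
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^step)
    vhat <- p$v / (1 - beta2^step)
    p$w <- p$w - lr * mhat / (sqrt(vhat) + eps)
  }
}

heInit <- function(nr, nc, fanIn) matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)

## broadcast a length-C vector over n rows of an n x C matrix
rowRep <- function(v, n) rep(v, each = n)

## ---- graph ----------------------------------------------------------------

newGraph <- function() {
  G <- new.env(parent = emptyenv())
  G$nodes <- list()
  G$params <- list()
  G
}

addNode <- function(G, op, inputs = integer(0), module = NULL) {
  inputs <- as.integer(inputs)  # force before id: inputs may create nodes
  force(module)
  id <- length(G$nodes) + 1L
  st <- new.env(parent = emptyenv())
  G$nodes[[id]] <- list(op = op, inputs = as.integer(inputs),
                        module = module, st = st)
  if (!is.null(module) && !is.null(module$params))
    G$params <- c(G$params, module$params)
  id
}

## module constructors: each returns list(params = <list of param envs>, ...)

convModule <- function(cin, cout, k, stride = 1L, dilation = 1L) {
  W <- newParam(heInit(k * k * cin, cout, k * k * cin))
  b <- newParam(numeric(cout))
  list(params = list(W, b), W = W, b = b, cin = cin, cout = cout,
       k = as.integer(k), stride = as.integer(stride),
       dilation = as.integer(dilation))
}

dwConvModule <- function(ch, k, stride = 1L, dilation = 1L) {
  W <- newParam(matrix(rnorm(k * k * ch, sd = sqrt(2 / (k * k))), k * k, ch))
  b <- newParam(numeric(ch))
  list(params = list(W, b), W = W, b = b, ch = ch, k = as.integer(k),
       stride = as.integer(stride), dilation = as.integer(dilation))
}

normModule <- function(ch) {
  gamma <- newParam(rep(1, ch)); beta <- newParam(numeric(ch))
  list(params = list(gamma, beta), gamma = gamma, beta = beta, eps = 1e-5)
}

## ---- forward / backward per op ---------------------------------------------

opForward <- function(node, ins, train) {
  st <- node$st; mod <- node$module
  switch(node$op,
    conv = {
      t1 <- ins[[1]]
      g <- convGeom(t1$H, t1$W, mod$k, mod$stride, mod$dilation)
      Xpad <- rbind(t1$x, 0)
      n <- nrow(g$idx)
      y <- matrix(rowRep(mod$b$w, n), n, mod$cout)
      kk <- mod$k * mod$k
      for (o in seq_len(kk)) {
        Wo <- mod$W$w[((o - 1L) * mod$cin + 1L):(o * mod$cin), , drop = FALSE]
        y <- y + Xpad[g$idx[, o], , drop = FALSE] %*% Wo
      }
      st$Xpad <- Xpad; st$g <- g; st$H <- t1$H; st$W <- t1$W
      tensor(y, g$Hout, g$Wout)
    },
    dwconv = {
      t1 <- ins[[1]]
      g <- convGeom(t1$H, t1$W, mod$k, mod$stride, mod$dilation)
      Xpad <- rbind(t1$x, 0)
      n <- nrow(g$idx)
      y <- matrix(rowRep(mod$b$w, n), n, mod$ch)
      for (o in seq_len(mod$k * mod$k))
        y <- y + Xpad[g$idx[, o], , drop = FALSE] * rowRep(mod$W$w[o, ], n)
      st$Xpad <- Xpad; st$g <- g; st$H <- t1$H; st$W <- t1$W
      tensor(y, g$Hout, g$Wout)
    },
    norm = {
      t1 <- ins[[1]]; x <- t1$x; n <- nrow(x)
      mu <- colMeans(x)
      xc <- x - rowRep(mu, n)
      v <- colMeans(xc * xc)
      istd <- 1 / sqrt(v + mod$eps)
      xhat <- xc * rowRep(istd, n)
      st$xhat <- xhat; st$istd <- istd
      tensor(xhat * rowRep(mod$gamma$w, n) + rowRep(mod$beta$w, n), t1$H, t1$W)
    },
    relu = {
      t1 <- ins[[1]]
      st$mask <- t1$x > 0
      tensor(t1$x * st$mask, t1$H, t1$W)
    },
    relu6 = {
      t1 <- ins[[1]]
      st$mask <- t1$x > 0 & t1$x < 6
      tensor(pmin(pmax(t1$x, 0), 6), t1$H, t1$W)
    },
    maxpool = {
      t1 <- ins[[1]]
      g <- convGeom(t1$H, t1$W, 3L, 2L, 1L)
      Xpad <- rbind(t1$x, -Inf)
      n <- nrow(g$idx); ch <- ncol(t1$x)
      y <- matrix(-Inf, n, ch); arg <- matrix(0L, n, ch)
      for (o in 1:9) {
        Xo <- Xpad[g$idx[, o], , drop = FALSE]
        upd <- Xo > y
        y[upd] <- Xo[upd]; arg[upd] <- o
      }
      st$g <- g; st$arg <- arg; st$H <- t1$H; st$W <- t1$W; st$ch <- ch
      tensor(y, g$Hout, g$Wout)
    },
    upsample = {
      t1 <- ins[[1]]
      H2 <- t1$H * node$st$factor; W2 <- t1$W * node$st$factor
      RH <- interpMatrix(t1$H, H2); RW <- interpMatrix(t1$W, W2)
      ch <- ncol(t1$x)
      y <- matrix(0, H2 * W2, ch)
      for (c in seq_len(ch))
        y[, c] <- as.vector(RH %*% matrix(t1$x[, c], t1$H, t1$W) %*% t(RW))
      st$RH <- RH; st$RW <- RW; st$H <- t1$H; st$W <- t1$W
      tensor(y, H2, W2)
    },
    gap = {
      t1 <- ins[[1]]
      st$n <- nrow(t1$x)
      tensor(matrix(colMeans(t1$x), 1L), 1L, 1L)
    },
    broadcast = {
      t1 <- ins[[1]]; ref <- ins[[2]]
      n <- nrow(ref$x)
      st$n <- n
      tensor(matrix(rowRep(as.vector(t1$x), n), n), ref$H, ref$W)
    },
    add = {
      tensor(ins[[1]]$x + ins[[2]]$x, ins[[1]]$H, ins[[1]]$W)
    },
    concat = {
      st$widths <- vapply(ins, function(t) ncol(t$x), integer(1))
      tensor(do.call(cbind, lapply(ins, `[[`, "x")), ins[[1]]$H, ins[[1]]$W)
    },
    input = ins[[1]],
    stop("unknown op ", node$op)
  )
}

opBackward <- function(node, dOut) {
  st <- node$st; mod <- node$module
  switch(node$op,
    conv = {
      g <- st$g; HW <- st$H * st$W
      cin <- mod$cin
      dX <- matrix(0, HW, cin)
      kk <- mod$k * mod$k
      mod$b$g <- mod$b$g + colSums(dOut)
      for (o in seq_len(kk)) {
        idx <- g$idx[, o]
        rows <- ((o - 1L) * cin + 1L):(o * cin)
        mod$W$g[rows, ] <- mod$W$g[rows, ] +
          crossprod(st$Xpad[idx, , drop = FALSE], dOut)
        Wo <- mod$W$w[rows, , drop = FALSE]
        contrib <- tcrossprod(dOut, Wo)
        valid <- idx <= HW
        tgt <- idx[valid]
        dX[tgt, ] <- dX[tgt, ] + contrib[valid, , drop = FALSE]
      }
      list(dX)
    },
    dwconv = {
      g <- st$g; HW <- st$H * st$W
      n <- nrow(dOut)
      dX <- matrix(0, HW, mod$ch)
      mod$b$g <- mod$b$g + colSums(dOut)
      for (o in seq_len(mod$k * mod$k)) {
        idx <- g$idx[, o]
        Xo <- st$Xpad[idx, , drop = FALSE]
        mod$W$g[o, ] <- mod$W$g[o, ] + colSums(Xo * dOut)
        contrib <- dOut * rowRep(mod$W$w[o, ], n)
        valid <- idx <= HW
        tgt <- idx[valid]
        dX[tgt, ] <- dX[tgt, ] + contrib[valid, , drop = FALSE]
      }
      list(dX)
    },
    norm = {
      xhat <- st$xhat; n <- nrow(dOut)
      mod$gamma$g <- mod$gamma$g + colSums(dOut * xhat)
      mod$beta$g <- mod$beta$g + colSums(dOut)
      dxhat <- dOut * rowRep(mod$gamma$w, n)
      s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
      dx <- (dxhat - rowRep(s1 / n, n) - xhat * rowRep(s2 / n, n)) *
        rowRep(st$istd, n)
      list(dx)
    },
    relu = list(dOut * st$mask),
    relu6 = list(dOut * st$mask),
    maxpool = {
      g <- st$g; HW <- st$H * st$W
      dX <- matrix(0, HW, st$ch)
      for (o in 1:9) {
        sel <- st$arg == o
        if (!any(sel)) next
        contrib <- dOut * sel
        idx <- g$idx[, o]
        valid <- idx <= HW
        tgt <- idx[valid]
        dX[tgt, ] <- dX[tgt, ] + contrib[valid, , drop = FALSE]
      }
      list(dX)
    },
    upsample = {
      ch <- ncol(dOut)
      H2 <- nrow(st$RH); W2 <- nrow(st$RW)
      dX <- matrix(0, st$H * st$W, ch)
      for (c in seq_len(ch))
        dX[, c] <- as.vector(crossprod(st$RH, matrix(dOut[, c], H2, W2)) %*% st$RW)
      list(dX)
    },
    gap = list(matrix(as.vector(dOut), st$n, ncol(dOut), byrow = TRUE) / st$n),
    broadcast = list(matrix(colSums(dOut), 1L), NULL),
    add = list(dOut, dOut),
    concat = {
      ends <- cumsum(st$widths)
      starts <- c(1L, head(ends, -1L) + 1L)
      lapply(seq_along(st$widths), function(i)
        dOut[, starts[i]:ends[i], drop = FALSE])
    },
    input = list(NULL),
    stop("unknown op ", node$op)
  )
}

## Evaluate the graph on input tensor `x`; returns list(values) keyed by id.
graphForward <- function(G, x, train = FALSE) {
  vals <- vector("list", length(G$nodes))
  for (id in seq_along(G$nodes)) {
    node <- G$nodes[[id]]
    ins <- if (node$op == "input") list(x) else vals[node$inputs]
    vals[[id]] <- opForward(node, ins, train)
  }
  vals
}

## Backpropagate dLoss (matrix matching the output node's x) through the tape.
graphBackward <- function(G, vals, dLoss, outId = length(G$nodes)) {
  grads <- vector("list", length(G$nodes))
  grads[[outId]] <- dLoss
  for (id in rev(seq_len(outId))) {
    d <- grads[[id]]
    if (is.null(d)) next
    node <- G$nodes[[id]]
    dIns <- opBackward(node, d)
    for (j in seq_along(node$inputs)) {
      di <- dIns[[j]]
      if (is.null(di)) next
      tgt <- node$inputs[j]
      grads[[tgt]] <- if (is.null(grads[[tgt]])) di else grads[[tgt]] + di
    }
    grads[id] <- list(NULL)   # free memory as we go
  }
  invisible(NULL)
}

## Mean softmax cross-entropy over 3 classes and its gradient.
## logits: n x K matrix; labels: integer vector in 0..K-1.
softmaxXent <- function(logits, labels) {
  n <- nrow(logits)
  m <- do.call(pmax, lapply(seq_len(ncol(logits)), function(j) logits[, j]))
  e <- exp(logits - m)
  Z <- rowSums(e)
  li <- cbind(seq_len(n), labels + 1L)
  loss <- mean(log(Z) - (logits[li] - m))
  dl <- e / Z
  dl[li] <- dl[li] - 1
  list(loss = loss, grad = dl / n)
}
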