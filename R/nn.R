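# Minimal convolutional-network engine: single-sample H x W x C tensors,
# im2col/col2im convolutions (src/im2col.cpp), manual backprop, Adam.
# Sized for patch-scale generators/discriminators; weights are drawn from
# the RNG stream active at construction time (callers wrap in withSeed()).

nnConv <- function(cin, cout, k, stride = 1L, pad = 0L) {
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(rnorm(k * k * cin * cout, 0, 0.02), k * k * cin, cout),
       b = numeric(cout))
}

# Transpose convolution; weight is (k*k*cout) x cin so its forward pass is
# the adjoint (col2im scatter) of a regular convolution.
nnConvT <- function(cin, cout, k = 3L, stride = 2L, pad = 1L, outPad = 1L) {
  list(type = "convT", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       outPad = as.integer(outPad),
       W = matrix(rnorm(k * k * cout * cin, 0, 0.02), k * k * cout, cin),
       b = numeric(cout))
}

nnInstanceNorm <- function() list(type = "inorm", eps = 1e-5)
nnReLU <- function() list(type = "relu")
nnLeakyReLU <- function(slope = 0.2) list(type = "lrelu", slope = slope)
nnTanh <- function() list(type = "tanh")
nnPadReflect <- function(p) list(type = "reflpad", p = as.integer(p))

nnResBlock <- function(ch) {
  list(type = "res",
       layers = list(nnPadReflect(1L), nnConv(ch, ch, 3L), nnInstanceNorm(),
                     nnReLU(), nnPadReflect(1L), nnConv(ch, ch, 3L),
                     nnInstanceNorm()))
}

reflectIndex <- function(n, p) {
  # PyTorch-style reflection (no edge duplication): -1 -> 1, n -> n-2 (0-based)
  i <- seq.int(-p, n - 1L + p)
  i[i < 0L] <- -i[i < 0L]
  i[i >= n] <- 2L * n - 2L - i[i >= n]
  i + 1L
}

layerForward <- function(layer, x) {
  d <- dim(x)
  switch(layer$type,
    conv = {
      k <- layer$k; s <- layer$stride; p <- layer$pad
      Ho <- (d[1] + 2L * p - k) %/% s + 1L
      Wo <- (d[2] + 2L * p - k) %/% s + 1L
      cols <- .c_im2col(x, d[1], d[2], d[3], k, k, s, s, p, p)
      ymat <- crossprod(layer$W, cols) + layer$b
      list(out = array(t(ymat), dim = c(Ho, Wo, layer$cout)),
           cache = list(cols = cols, din = d))
    },
    convT = {
      k <- layer$k; s <- layer$stride; p <- layer$pad
      Ho <- (d[1] - 1L) * s - 2L * p + k + layer$outPad
      Wo <- (d[2] - 1L) * s - 2L * p + k + layer$outPad
      xmat <- t(matrix(x, d[1] * d[2], d[3]))
      dcols <- layer$W %*% xmat
      y <- .c_col2im(dcols, Ho, Wo, layer$cout, k, k, s, s, p, p)
      y <- y + rep(layer$b, each = Ho * Wo)
      list(out = y, cache = list(xmat = xmat, din = d, dout = c(Ho, Wo)))
    },
    inorm = {
      n <- d[1] * d[2]
      xm <- matrix(x, n, d[3])
      mu <- colMeans(xm)
      xc <- xm - rep(mu, each = n)
      v <- colSums(xc * xc) / n
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- xc * rep(invstd, each = n)
      list(out = array(xhat, dim = d),
           cache = list(xhat = xhat, invstd = invstd, d = d))
    },
    relu = {
      m <- x > 0
      list(out = x * m, cache = m)
    },
    lrelu = {
      m <- x > 0
      list(out = x * m + layer$slope * (x * !m), cache = m)
    },
    tanh = {
      y <- tanh(x)
      list(out = y, cache = y)
    },
    reflpad = {
      ri <- reflectIndex(d[1], layer$p)
      ci <- reflectIndex(d[2], layer$p)
      list(out = x[ri, ci, , drop = FALSE], cache = list(d = d))
    },
    res = {
      h <- x
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        f <- layerForward(layer$layers[[i]], h)
        h <- f$out
        caches[[i]] <- f$cache
      }
      list(out = x + h, cache = caches)
    },
    stop("unknown layer type: ", layer$type))
}

layerBackward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      d <- cache$din
      k <- layer$k; s <- layer$stride; p <- layer$pad
      dd <- dim(dy)
      dymat <- t(matrix(dy, dd[1] * dd[2], dd[3]))
      dW <- cache$cols %*% t(dymat)
      db <- rowSums(dymat)
      dcols <- layer$W %*% dymat
      dx <- .c_col2im(dcols, d[1], d[2], d[3], k, k, s, s, p, p)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    convT = {
      d <- cache$din
      k <- layer$k; s <- layer$stride; p <- layer$pad
      Ho <- cache$dout[1]; Wo <- cache$dout[2]
      dyCols <- .c_im2col(dy, Ho, Wo, layer$cout, k, k, s, s, p, p)
      dxmat <- crossprod(layer$W, dyCols)
      dx <- array(t(dxmat), dim = d)
      dW <- dyCols %*% t(cache$xmat)
      db <- colSums(matrix(dy, Ho * Wo, layer$cout))
      list(dx = dx, grads = list(W = dW, b = db))
    },
    inorm = {
      d <- cache$d
      n <- d[1] * d[2]
      dym <- matrix(dy, n, d[3])
      mh <- colMeans(dym)
      mxh <- colMeans(dym * cache$xhat)
      dx <- (dym - rep(mh, each = n) - cache$xhat * rep(mxh, each = n)) *
        rep(cache$invstd, each = n)
      list(dx = array(dx, dim = d), grads = NULL)
    },
    relu = list(dx = dy * cache, grads = NULL),
    lrelu = list(dx = dy * cache + layer$slope * (dy * !cache), grads = NULL),
    tanh = list(dx = dy * (1 - cache^2), grads = NULL),
    reflpad = {
      d <- cache$d
      p <- layer$p
      ri <- reflectIndex(d[1], p)
      ci <- reflectIndex(d[2], p)
      dd <- dim(dy)
      # scatter-add duplicated border indices, one axis at a time
      a <- rowsum(matrix(dy, dd[1], dd[2] * dd[3]), ri)        # rows -> H
      a <- array(a, dim = c(d[1], dd[2], d[3]))
      a <- aperm(a, c(2L, 1L, 3L))
      a <- rowsum(matrix(a, dd[2], d[1] * d[3]), ci)           # cols -> W
      dx <- aperm(array(a, dim = c(d[2], d[1], d[3])), c(2L, 1L, 3L))
      list(dx = dx, grads = NULL)
    },
    res = {
      g <- vector("list", length(layer$layers))
      dh <- dy
      for (i in rev(seq_along(layer$layers))) {
        b <- layerBackward(layer$layers[[i]], cache[[i]], dh)
        dh <- b$dx
        g[i] <- list(b$grads)
      }
      list(dx = dy + dh, grads = g)
    },
    stop("unknown layer type: ", layer$type))
}

netForward <- function(net, x, keepCache = TRUE) {
  caches <- if (keepCache) vector("list", length(net$layers)) else NULL
  h <- x
  for (i in seq_along(net$layers)) {
    f <- layerForward(net$layers[[i]], h)
    h <- f$out
    if (keepCache) caches[[i]] <- f$cache
  }
  list(out = h, caches = caches)
}

netBackward <- function(net, caches, dy) {
  grads <- vector("list", length(net$layers))
  dh <- dy
  for (i in rev(seq_along(net$layers))) {
    b <- layerBackward(net$layers[[i]], caches[[i]], dh)
    dh <- b$dx
    grads[i] <- list(b$grads)
  }
  list(dx = dh, grads = grads)
}

# Elementwise sum of two grad structures (same shape as net layers).
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) { a[[i]] <- b[[i]]; next }
    if (!is.null(a[[i]]$W)) {
      a[[i]]$W <- a[[i]]$W + b[[i]]$W
      a[[i]]$b <- a[[i]]$b + b[[i]]$b
    } else {
      a[[i]] <- addGrads(a[[i]], b[[i]])  # residual sub-grads
    }
  }
  a
}

adamInitState <- function(net) {
  st <- lapply(net$layers, function(l) {
    if (l$type %in% c("conv", "convT"))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else if (l$type == "res")
      adamInitState(list(layers = l$layers))$layers
    else NULL
  })
  list(layers = st, t = 0L)
}

adamUpdateLayers <- function(layers, grads, st, lr, b1, b2, eps, bc1, bc2) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (l$type %in% c("conv", "convT")) {
      s <- st[[i]]
      s$mW <- b1 * s$mW + (1 - b1) * g$W
      s$vW <- b2 * s$vW + (1 - b2) * g$W^2
      s$mb <- b1 * s$mb + (1 - b1) * g$b
      s$vb <- b2 * s$vb + (1 - b2) * g$b^2
      l$W <- l$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
      l$b <- l$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
      layers[[i]] <- l
      st[[i]] <- s
    } else if (l$type == "res") {
      r <- adamUpdateLayers(l$layers, g, st[[i]], lr, b1, b2, eps, bc1, bc2)
      l$layers <- r$layers
      layers[[i]] <- l
      st[[i]] <- r$st
    }
  }
  list(layers = layers, st = st)
}

adamStep <- function(net, grads, state, lr, b1 = 0.5, b2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  r <- adamUpdateLayers(net$layers, grads, state$layers, lr, b1, b2, eps,
                        bc1, bc2)
  net$layers <- r$layers
  state$layers <- r$st
  list(net = net, state = state)
}

# Flatten all weights into one numeric vector (testing / checkpoint digests).
netWeightVector <- function(net) {
  acc <- c()
  walk <- function(layers) {
    for (l in layers) {
      if (l$type %in% c("conv", "convT")) acc <<- c(acc, as.vector(l$W), l$b)
      else if (l$type == "res") walk(l$layers)
    }
  }
  walk(net$layers)
  acc
}
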