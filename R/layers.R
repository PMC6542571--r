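# Differentiable layer primitives over (H, W, C, N) arrays. Convolutions
# and pooling run in compiled code (see src/ops.cpp); batch normalisation,
# ReLU and the classifier head are vectorised R. Every *Forward returns the
# output plus the cache its *Backward needs.

BN_MOMENTUM <- 0.99
BN_EPS <- 1e-5

# per-channel mean of an (H, W, C, N) array
chanMean <- function(x) {
  d <- dim(x)
  cm <- colMeans(matrix(x, d[1] * d[2]))
  rowMeans(matrix(cm, d[3]))
}

chanSum <- function(x) {
  d <- dim(x)
  cs <- colSums(matrix(x, d[1] * d[2]))
  rowSums(matrix(cs, d[3]))
}

# broadcast a per-channel vector over an (H, W, C, N)-shaped matrix view
chanRep <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

bnForward <- function(x, p, st, train) {
  d <- dim(x)
  if (train) {
    mu <- chanMean(x)
    var <- chanMean(x * x) - mu^2
    st$mean <- BN_MOMENTUM * st$mean + (1 - BN_MOMENTUM) * mu
    st$var <- BN_MOMENTUM * st$var + (1 - BN_MOMENTUM) * var
  } else {
    mu <- st$mean
    var <- st$var
  }
  invstd <- 1 / sqrt(var + BN_EPS)
  xhat <- (x - chanRep(mu, d)) * chanRep(invstd, d)
  y <- xhat * chanRep(p$gamma, d) + chanRep(p$beta, d)
  list(y = y, cache = list(xhat = xhat, invstd = invstd), st = st)
}

bnBackward <- function(cache, p, dy) {
  d <- dim(dy)
  m <- d[1] * d[2] * d[4]
  dbeta <- chanSum(dy)
  dgamma <- chanSum(dy * cache$xhat)
  coef <- chanRep(p$gamma * cache$invstd, d)
  dx <- coef * (dy - chanRep(dbeta / m, d) -
                  cache$xhat * chanRep(dgamma / m, d))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# One composite function: basic = BN-ReLU-Conv(h x w, f, s);
# bottleneck = BN-ReLU-Conv(1 x 1, 4f, 1)-BN-ReLU-Conv(h x w, f, s).
compositeForward <- function(x, p, st, cfg, train) {
  pad <- (cfg$h - 1L) %/% 2L
  if (cfg$variant == "basic") {
    b1 <- bnForward(x, p$bn, st$bn, train)
    r1 <- pmax(b1$y, 0)
    y <- conv2d_forward_cpp(r1, p$conv$W, p$conv$b, cfg$s, pad)
    st$bn <- b1$st
    list(y = y, st = st,
         cache = list(b1 = b1$cache, r1 = r1, mask1 = b1$y > 0))
  } else {
    b1 <- bnForward(x, p$bn1, st$bn1, train)
    r1 <- pmax(b1$y, 0)
    h1 <- conv2d_forward_cpp(r1, p$conv1$W, p$conv1$b, 1L, 0L)
    b2 <- bnForward(h1, p$bn2, st$bn2, train)
    r2 <- pmax(b2$y, 0)
    y <- conv2d_forward_cpp(r2, p$conv2$W, p$conv2$b, cfg$s, pad)
    st$bn1 <- b1$st; st$bn2 <- b2$st
    list(y = y, st = st,
         cache = list(b1 = b1$cache, mask1 = b1$y > 0, r1 = r1, h1 = h1,
                      b2 = b2$cache, mask2 = b2$y > 0, r2 = r2))
  }
}

compositeBackward <- function(cache, p, cfg, dy) {
  pad <- (cfg$h - 1L) %/% 2L
  if (cfg$variant == "basic") {
    cb <- conv2d_backward_cpp(cache$r1, p$conv$W, dy, cfg$s, pad)
    dr1 <- cb$dx * cache$mask1
    bb <- bnBackward(cache$b1, p$bn, dr1)
    list(dx = bb$dx,
         grads = list(bn = bb$grads, conv = list(W = cb$dw, b = cb$db)))
  } else {
    cb2 <- conv2d_backward_cpp(cache$r2, p$conv2$W, dy, cfg$s, pad)
    dr2 <- cb2$dx * cache$mask2
    bb2 <- bnBackward(cache$b2, p$bn2, dr2)
    cb1 <- conv2d_backward_cpp(cache$r1, p$conv1$W, bb2$dx, 1L, 0L)
    dr1 <- cb1$dx * cache$mask1
    bb1 <- bnBackward(cache$b1, p$bn1, dr1)
    list(dx = bb1$dx,
         grads = list(bn1 = bb1$grads, conv1 = list(W = cb1$dw, b = cb1$db),
                      bn2 = bb2$grads, conv2 = list(W = cb2$dw, b = cb2$db)))
  }
}

bindChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Dense block: layer l consumes the concatenation of the block input and
# all previous in-block outputs; the block output is the full concatenation.
denseBlockForward <- function(x, p, st, cfg, train) {
  acc <- x
  caches <- vector("list", cfg$d)
  for (j in seq_len(cfg$d)) {
    cf <- compositeForward(acc, p$layers[[j]], st$layers[[j]], cfg, train)
    caches[[j]] <- cf$cache
    st$layers[[j]] <- cf$st
    acc <- bindChannels(acc, cf$y)
  }
  list(y = acc, st = st, caches = caches, inChannels = dim(x)[3])
}

denseBlockBackward <- function(fw, p, cfg, dacc) {
  c0 <- fw$inChannels
  f <- cfg$f
  grads <- vector("list", cfg$d)
  for (j in rev(seq_len(cfg$d))) {
    sel <- c0 + (j - 1L) * f + seq_len(f)
    dyj <- dacc[, , sel, , drop = FALSE]
    cb <- compositeBackward(fw$caches[[j]], p$layers[[j]], cfg, dyj)
    grads[[j]] <- cb$grads
    dacc <- dacc[, , seq_len(c0 + (j - 1L) * f), , drop = FALSE] + cb$dx
  }
  list(dx = dacc, grads = list(layers = grads))
}

softmaxCols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

crossEntropy <- function(probs, labels) {
  -mean(log(pmax(probs[cbind(labels + 1L, seq_along(labels))], 1e-12)))
}
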