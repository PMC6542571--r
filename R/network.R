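# DenseNet construction: declarative stage specifications, the two
# full-scale presets, channel/spatial audit, weight initialisation and the
# forward/backward pass over a whole network.

#' Declarative DenseNet specification
#'
#' Builds the standard stage chain: an opening basic dense block (stem,
#' one layer of 2k filters, 7 x 7 kernel, stride 2), a 3 x 3 stride-2 max
#' pooling, alternating bottleneck dense blocks and transition layers, a
#' closing bottleneck dense block, global average pooling and a 6-way
#' softmax classifier. All bottleneck blocks use 3 x 3 stride-1 kernels
#' with f = k filters; transition layers compress channels by the factor
#' theta and halve the spatial side.
#'
#' @param name spec name.
#' @param inputSide input image side in px.
#' @param k growth parameter (filters per dense-block convolution).
#' @param dbDepths integer vector: layer counts of the inner bottleneck
#'   dense blocks, each followed by a transition layer.
#' @param closingDepth layer count of the closing dense block.
#' @param theta transition-layer compression factor in (0, 1].
#' @param nClasses classifier width (6: reject class + 5 stages).
#' @return A \linkS4class{NetworkSpec}.
#' @examples
#' spec <- denseNetSpec("toy", 64L, k = 4L, dbDepths = c(2L, 2L),
#'                      closingDepth = 2L)
#' channelLedger(spec)
#' @export
denseNetSpec <- function(name, inputSide, k, dbDepths, closingDepth,
                         theta = 0.5, nClasses = 6L) {
  stages <- list(list(type = "DBa", h = 7L, w = 7L, s = 2L, f = 2L * k,
                      d = 1L, variant = "basic"),
                 list(type = "MPL", h = 3L, w = 3L, s = 2L))
  for (d in dbDepths) {
    stages <- c(stages, list(
      list(type = "DBb", h = 3L, w = 3L, s = 1L, f = k, d = as.integer(d),
           variant = "bottleneck"),
      list(type = "TL", theta = theta)))
  }
  stages <- c(stages, list(
    list(type = "DBb", h = 3L, w = 3L, s = 1L, f = k,
         d = as.integer(closingDepth), variant = "bottleneck"),
    list(type = "GAP"),
    list(type = "C", units = as.integer(nClasses))))
  new("NetworkSpec", name = name, inputSide = as.integer(inputSide),
      inputChannels = 1L, k = as.integer(k), theta = theta, stages = stages)
}

#' DenseNet-512 preset
#'
#' Classifies 512 x 512 px images: k = 20, inner dense blocks of depths
#' 6, 9, 12 and 15 (each followed by a transition layer), closing block of
#' depth 18, theta = 0.5. The classifier consumes 602 channels.
#' @return A \linkS4class{NetworkSpec}.
#' @export
denseNet512Spec <- function() {
  denseNetSpec("DenseNet-512", 512L, k = 20L,
               dbDepths = c(6L, 9L, 12L, 15L), closingDepth = 18L)
}

#' DenseNet-1024 preset
#'
#' Classifies 1024 x 1024 px images: k = 15, inner dense blocks of depths
#' 6, 8, 8, 10 and 15, closing block of depth 15, theta = 0.5. The
#' classifier consumes 401 channels.
#' @return A \linkS4class{NetworkSpec}.
#' @export
denseNet1024Spec <- function() {
  denseNetSpec("DenseNet-1024", 1024L, k = 15L,
               dbDepths = c(6L, 8L, 8L, 10L, 15L), closingDepth = 15L)
}

#' Tiny desk-scale preset
#'
#' A scaled-down network for CPU experimentation and testing: 128 px
#' input, k = 4, two inner dense blocks of depth 2, closing depth 2.
#' @return A \linkS4class{NetworkSpec}.
#' @export
tinyDenseNetSpec <- function() {
  denseNetSpec("DenseNet-tiny", 128L, k = 4L, dbDepths = c(2L, 2L),
               closingDepth = 2L)
}

convOut <- function(side, k, s, pad) (side + 2L * pad - k) %/% s + 1L

#' Channel ledger of a network specification
#'
#' Output channel count after every stage, following the concatenation rule
#' of dense blocks (out = in + d * f) and the compression of transition
#' layers (out = floor(theta * in)). The stem's max pooling consumes only
#' the opening convolution's 2k feature maps.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return named integer vector (names are stage types); the last entry is
#'   the classifier output width.
#' @export
channelLedger <- function(spec) {
  ch <- spec@inputChannels
  out <- integer(0)
  for (st in spec@stages) {
    ch <- switch(st$type,
      DBa = st$f,                       # stem hand-off: conv output only
      MPL = ch,
      DBb = ch + st$d * st$f,
      TL = as.integer(floor(st$theta * ch)),
      GAP = ch,
      C = st$units)
    out <- c(out, ch)
  }
  names(out) <- vapply(spec@stages, `[[`, "", "type")
  out
}

#' Spatial side trace of a network specification
#'
#' The feature-map side after every stage. Errors if any stage underflows
#' (side below 1) or a transition layer receives an odd side, reporting the
#' stage trace up to the failure.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return named integer vector of sides; GAP reduces to 1.
#' @export
spatialTrace <- function(spec) {
  side <- spec@inputSide
  out <- integer(0)
  for (i in seq_along(spec@stages)) {
    st <- spec@stages[[i]]
    side <- switch(st$type,
      DBa = convOut(side, st$h, st$s, (st$h - 1L) %/% 2L),
      MPL = convOut(side, st$h, st$s, 1L),
      DBb = side,
      TL = {
        if (side %% 2L != 0L)
          stop("transition layer at stage ", i, " receives odd side ", side,
               " (trace: ", paste(out, collapse = " -> "), ")")
        side %/% 2L
      },
      GAP = 1L,
      C = 1L)
    if (side < 1L)
      stop("spatial underflow at stage ", i, " (trace: ",
           paste(out, collapse = " -> "), ")")
    out <- c(out, side)
  }
  names(out) <- vapply(spec@stages, `[[`, "", "type")
  out
}

#' Per-stage audit table of a network specification
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return data.frame with stage type, kernel h/w, stride, filters, depth,
#'   output channels and output side.
#' @export
describeNetwork <- function(spec) {
  g <- function(st, f) if (!is.null(st[[f]])) st[[f]] else NA_integer_
  data.frame(
    stage = seq_along(spec@stages),
    type = vapply(spec@stages, `[[`, "", "type"),
    h = vapply(spec@stages, g, 0L, "h"),
    w = vapply(spec@stages, g, 0L, "w"),
    s = vapply(spec@stages, g, 0L, "s"),
    f = vapply(spec@stages, g, 0L, "f"),
    d = vapply(spec@stages, g, 0L, "d"),
    outChannels = unname(channelLedger(spec)),
    outSide = unname(spatialTrace(spec)))
}

heConv <- function(kh, kw, cin, f) {
  array(stats::rnorm(kh * kw * cin * f, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, f))
}

initBN <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
initBNState <- function(c) list(mean = rep(0, c), var = rep(1, c))

initComposite <- function(cfg, cin) {
  if (cfg$variant == "basic") {
    list(p = list(bn = initBN(cin),
                  conv = list(W = heConv(cfg$h, cfg$w, cin, cfg$f),
                              b = rep(0, cfg$f))),
         st = list(bn = initBNState(cin)))
  } else {
    mid <- 4L * cfg$f
    list(p = list(bn1 = initBN(cin),
                  conv1 = list(W = heConv(1L, 1L, cin, mid),
                               b = rep(0, mid)),
                  bn2 = initBN(mid),
                  conv2 = list(W = heConv(cfg$h, cfg$w, mid, cfg$f),
                               b = rep(0, cfg$f))),
         st = list(bn1 = initBNState(cin), bn2 = initBNState(mid)))
  }
}

#' Build a DenseNet classifier from a specification
#'
#' Instantiates all weights (He fan-in initialisation for convolutions,
#' unit-gamma/zero-beta batch norms, zero classifier bias) and verifies the
#' stage chain: the spatial trace must stay positive and transition layers
#' must receive even sides.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param rngSeed integer seed for weight initialisation.
#' @return A \linkS4class{DenseNetModel}.
#' @examples
#' m <- buildNetwork(denseNetSpec("toy", 32L, 2L, c(1L), 1L), rngSeed = 1)
#' @export
buildNetwork <- function(spec, rngSeed = 1L) {
  spatialTrace(spec)   # errors on underflow / odd transition input
  withSeed(rngSeed, {
    ch <- spec@inputChannels
    params <- list(); state <- list()
    for (i in seq_along(spec@stages)) {
      st <- spec@stages[[i]]
      if (st$type %in% c("DBa", "DBb")) {
        lp <- vector("list", st$d); ls <- vector("list", st$d)
        cin <- ch
        for (j in seq_len(st$d)) {
          ini <- initComposite(st, cin)
          lp[[j]] <- ini$p; ls[[j]] <- ini$st
          cin <- cin + st$f
        }
        params[[i]] <- list(layers = lp)
        state[[i]] <- list(layers = ls)
        ch <- if (st$type == "DBa") st$f else ch + st$d * st$f
      } else if (st$type == "TL") {
        fout <- as.integer(floor(st$theta * ch))
        params[[i]] <- list(bn = initBN(ch),
                            conv = list(W = heConv(1L, 1L, ch, fout),
                                        b = rep(0, fout)))
        state[[i]] <- list(bn = initBNState(ch))
        ch <- fout
      } else if (st$type == "C") {
        params[[i]] <- list(W = matrix(stats::rnorm(ch * st$units, 0,
                                                    sqrt(1 / ch)),
                                       ch, st$units),
                            b = rep(0, st$units))
        state[[i]] <- list()
      } else {
        params[[i]] <- list(); state[[i]] <- list()
      }
    }
    new("DenseNetModel", spec = spec, params = params, state = state,
        opt = list())
  })
}

#' @export
setMethod("show", "DenseNetModel", function(object) {
  spec <- object@spec
  cat(sprintf("DenseNetModel '%s': input %d x %d x %d, k = %d, theta = %g\n",
              spec@name, spec@inputSide, spec@inputSide, spec@inputChannels,
              spec@k, spec@theta))
  print(describeNetwork(spec))
})

# Full forward pass. Returns class probabilities (6 x N), per-stage caches
# for the backward pass, and updated batch-norm state.
networkForward <- function(model, x, train = FALSE) {
  spec <- model@spec
  state <- model@state
  caches <- vector("list", length(spec@stages))
  for (i in seq_along(spec@stages)) {
    st <- spec@stages[[i]]
    if (st$type == "DBa") {
      cf <- compositeForward(x, model@params[[i]]$layers[[1]],
                             state[[i]]$layers[[1]], st, train)
      state[[i]]$layers[[1]] <- cf$st
      caches[[i]] <- cf$cache
      x <- cf$y
    } else if (st$type == "MPL") {
      mp <- maxpool_forward_cpp(x, st$h, st$s, 1L)
      caches[[i]] <- list(idx = mp$idx, xdim = dim(x))
      x <- mp$y
    } else if (st$type == "DBb") {
      fw <- denseBlockForward(x, model@params[[i]], state[[i]], st, train)
      state[[i]] <- fw$st
      caches[[i]] <- fw
      x <- fw$y
    } else if (st$type == "TL") {
      if (dim(x)[1] %% 2L != 0L) stop("odd side at transition layer ", i)
      b <- bnForward(x, model@params[[i]]$bn, state[[i]]$bn, train)
      state[[i]]$bn <- b$st
      r <- pmax(b$y, 0)
      h <- conv2d_forward_cpp(r, model@params[[i]]$conv$W,
                              model@params[[i]]$conv$b, 1L, 0L)
      caches[[i]] <- list(b = b$cache, mask = b$y > 0, r = r, hdim = dim(h))
      x <- avgpool2_forward_cpp(h)
    } else if (st$type == "GAP") {
      d <- dim(x)
      caches[[i]] <- list(xdim = d)
      x <- matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
    } else if (st$type == "C") {
      caches[[i]] <- list(g = x)
      x <- softmaxCols(crossprod(model@params[[i]]$W, x) +
                         model@params[[i]]$b)
    }
  }
  list(probs = x, caches = caches, state = state)
}

# Backward pass from softmax-gradient dz (6 x N, already divided by N).
networkBackward <- function(model, caches, dz) {
  spec <- model@spec
  grads <- vector("list", length(spec@stages))
  d <- NULL
  for (i in rev(seq_along(spec@stages))) {
    st <- spec@stages[[i]]
    if (st$type == "C") {
      g <- caches[[i]]$g
      grads[[i]] <- list(W = g %*% t(dz), b = rowSums(dz))
      d <- model@params[[i]]$W %*% dz
    } else if (st$type == "GAP") {
      xd <- caches[[i]]$xdim
      grads[[i]] <- list()
      d <- array(rep(as.numeric(d) / (xd[1] * xd[2]),
                     each = xd[1] * xd[2]), xd)
    } else if (st$type == "TL") {
      ca <- caches[[i]]
      dh <- avgpool2_backward_cpp(d, ca$hdim)
      cb <- conv2d_backward_cpp(ca$r, model@params[[i]]$conv$W, dh, 1L, 0L)
      dr <- cb$dx * ca$mask
      bb <- bnBackward(ca$b, model@params[[i]]$bn, dr)
      grads[[i]] <- list(bn = bb$grads, conv = list(W = cb$dw, b = cb$db))
      d <- bb$dx
    } else if (st$type == "DBb") {
      db <- denseBlockBackward(caches[[i]], model@params[[i]], st, d)
      grads[[i]] <- db$grads
      d <- db$dx
    } else if (st$type == "MPL") {
      grads[[i]] <- list()
      d <- maxpool_backward_cpp(caches[[i]]$idx, d, caches[[i]]$xdim)
    } else if (st$type == "DBa") {
      cb <- compositeBackward(caches[[i]], model@params[[i]]$layers[[1]],
                              st, d)
      grads[[i]] <- list(layers = list(cb$grads))
      d <- cb$dx
    }
  }
  grads
}

#' Class probability scores for a stack of images
#'
#' Runs the network in evaluation mode (batch-norm statistics frozen at
#' their running values) over an (H, W, 1, N) array or a list of matrices.
#'
#' @param model a trained \linkS4class{DenseNetModel}.
#' @param x (H, W, 1, N) array, a single matrix, or list of matrices.
#' @param batchSize inference batch size.
#' @return N x 6 matrix of class probabilities; every row sums to 1.
#' @export
predictScores <- function(model, x, batchSize = 16L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (is.list(x)) {
    side <- nrow(x[[1]])
    x <- array(unlist(x), c(side, side, 1L, length(x)))
  }
  if (dim(x)[1] != model@spec@inputSide)
    stop("image side ", dim(x)[1], " does not match network input side ",
         model@spec@inputSide)
  n <- dim(x)[4]
  out <- matrix(NA_real_, n, 6)
  for (start in seq(1L, n, by = batchSize)) {
    sel <- start:min(start + batchSize - 1L, n)
    fw <- networkForward(model, x[, , , sel, drop = FALSE], train = FALSE)
    out[sel, ] <- t(fw$probs)
  }
  colnames(out) <- paste0("class", 0:5)
  out
}
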