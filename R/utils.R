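#' @useDynLib myoStage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @import methods
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("rng seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps values in 32-bit integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483562) + 1L
}

# Median intensity of the one-pixel border frame; used as the neutral
# background level when rotations or compositing expose new canvas.
borderMedian <- function(px) {
  n <- nrow(px); m <- ncol(px)
  stats::median(c(px[1, ], px[n, ], px[, 1], px[, m]))
}

# Keys cubic convolution kernel, a = -0.5 (the classical bicubic filter).
cubicKernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Row-stochastic resampling matrix mapping `src` samples onto `dst` samples.
# For downscaling the kernel support is stretched by the scale factor so the
# filter also acts as an anti-alias low-pass, matching common imaging-library
# behaviour of bicubic resize.
bicubicWeights <- function(src, dst) {
  scale <- src / dst
  stretch <- max(scale, 1)
  support <- 2 * stretch
  A <- matrix(0, dst, src)
  for (i in seq_len(dst)) {
    centre <- (i - 0.5) * scale - 0.5       # 0-based source coordinate
    j0 <- max(0, floor(centre - support))
    j1 <- min(src - 1, ceiling(centre + support))
    j <- j0:j1
    w <- cubicKernel((j - centre) / stretch)
    s <- sum(w)
    if (s == 0) { w[] <- 0; w[which.min(abs(j - centre))] <- 1; s <- 1 }
    A[i, j + 1] <- w / s
  }
  A
}

# Separable bicubic resample of a square matrix to side `dst`.
resampleBicubic <- function(px, dst) {
  A <- bicubicWeights(nrow(px), dst)
  A %*% px %*% t(A)
}

# Nearest-neighbour resample (used for binary object masks).
resampleNearest <- function(m, dst) {
  src <- nrow(m)
  idx <- pmin(src, floor(((seq_len(dst) - 0.5) * src / dst)) + 1L)
  m[idx, idx, drop = FALSE]
}

fmtCount <- function(n) format(n, big.mark = ",", trim = TRUE)
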