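# Shared fixtures and independent oracles, all built in code.

# Cheap stand-in source image (e.g. 64 px) for count/bookkeeping tests that
# never look at realistic texture.
standinSource <- function(id, label, side = 64L, pxsize = 116) {
  px <- matrix(stats::runif(side * side, 0, 0.2), side, side)
  mask <- matrix(FALSE, side, side)
  if (label > 0) {
    lo <- round(side * 0.3); hi <- round(side * 0.65)
    mask[lo:hi, lo:hi] <- TRUE
    px[mask] <- 0.8
  }
  SourceImage(px, as.integer(label), pxsize, mask, sourceId = id)
}

# Pool with given per-class counts, classes 0..5.
standinPool <- function(counts, side = 64L) {
  pool <- list()
  for (cl in seq_along(counts) - 1L) {
    for (i in seq_len(counts[cl + 1L])) {
      pool[[length(pool) + 1L]] <-
        standinSource(sprintf("c%d_%03d", cl, i), cl, side)
    }
  }
  pool
}

# Independent channel recurrence oracle: walks a spec's stage list with the
# dense-block concatenation rule and transition-layer compression computed
# by hand, without calling the package's ledger.
recurrenceOracle <- function(spec) {
  ch <- spec@inputChannels
  out <- integer(0)
  for (st in spec@stages) {
    ch <- if (st$type == "DBa") st$f
      else if (st$type == "DBb") { m <- ch; for (j in seq_len(st$d)) m <- m + st$f; m }
      else if (st$type == "TL") as.integer(floor(st$theta * ch))
      else if (st$type == "C") st$units
      else ch
    out <- c(out, ch)
  }
  out
}

# Radial high-frequency spectral energy above a frequency cutoff (cycles/px).
hfEnergy <- function(px, fmin = 0.15) {
  n <- nrow(px)
  P <- Mod(stats::fft(px - mean(px)))^2
  f <- (0:(n - 1)) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  fr <- sqrt(outer(f^2, f^2, "+"))
  sum(P[fr > fmin])
}

# Direct triple-loop 2-D convolution oracle for one sample/filter.
convOracle <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; F <- dim(w)[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, F))
  for (f in seq_len(F)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- b[f]
    for (c in seq_len(C)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      hi <- (ho - 1) * stride - pad + ki
      wi <- (wo - 1) * stride - pad + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, c] * w[ki, kj, c, f]
    }
    y[ho, wo, f] <- acc
  }
  y
}

# Brute-force macro metrics oracle from raw label pairs.
metricsOracle <- function(true, predicted) {
  accs <- precs <- recs <- numeric(6)
  n <- length(true)
  for (cl in 0:5) {
    tp <- sum(true == cl & predicted == cl)
    fp <- sum(true != cl & predicted == cl)
    fn <- sum(true == cl & predicted != cl)
    tn <- n - tp - fp - fn
    accs[cl + 1] <- (tp + tn) / n
    precs[cl + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recs[cl + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  list(acc = 100 * mean(accs), prec = 100 * mean(precs),
       rec = 100 * mean(recs))
}
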