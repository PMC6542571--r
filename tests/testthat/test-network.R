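# DenseNet construction: preset fidelity, channel/spatial audit against an
# independent recurrence oracle, forward-pass contracts, gradient exactness.

test_that("the two full-scale presets match their published structure field for field", {
  d512 <- describeNetwork(denseNet512Spec())
  expect_equal(d512$type,
               c("DBa", "MPL", "DBb", "TL", "DBb", "TL", "DBb", "TL",
                 "DBb", "TL", "DBb", "GAP", "C"))
  expect_equal(d512$d[d512$type == "DBb"], c(6L, 9L, 12L, 15L, 18L))
  expect_equal(sum(d512$type == "DBb"), 5L)    # four inner + closing block
  expect_equal(d512$f[d512$type == "DBa"], 40L)          # 2k, k = 20
  expect_true(all(d512$f[d512$type == "DBb"] == 20L))
  expect_equal(d512$h[1:2], c(7L, 3L))                   # stem kernel, pool
  expect_equal(d512$s[1:2], c(2L, 2L))
  expect_true(all(d512$h[d512$type == "DBb"] == 3L))
  expect_true(all(d512$s[d512$type == "DBb"] == 1L))

  d1024 <- describeNetwork(denseNet1024Spec())
  expect_equal(d1024$type,
               c("DBa", "MPL", "DBb", "TL", "DBb", "TL", "DBb", "TL",
                 "DBb", "TL", "DBb", "TL", "DBb", "GAP", "C"))
  expect_equal(d1024$d[d1024$type == "DBb"], c(6L, 8L, 8L, 10L, 15L, 15L))
  expect_equal(d1024$f[d1024$type == "DBa"], 30L)        # 2k, k = 15
  expect_true(all(d1024$f[d1024$type == "DBb"] == 15L))
  expect_equal(denseNet512Spec()@theta, 0.5)
  expect_equal(denseNet1024Spec()@theta, 0.5)
})

test_that("channel ledgers match the independent recurrence oracle", {
  for (spec in list(denseNet512Spec(), denseNet1024Spec(),
                    tinyDenseNetSpec())) {
    expect_equal(unname(channelLedger(spec)), recurrenceOracle(spec))
  }
  # classifier inputs of the presets
  l512 <- channelLedger(denseNet512Spec())
  expect_equal(unname(l512[names(l512) == "GAP"]), 602L)
  l1024 <- channelLedger(denseNet1024Spec())
  expect_equal(unname(l1024[names(l1024) == "GAP"]), 401L)
  # the floor compression after the fourth inner block: floor(0.5 * 255)
  expect_true(127L %in% l1024)

  # property: 50 randomized small specs agree with the oracle and with the
  # weight shapes of the built model
  set.seed(20)
  for (r in 1:50) {
    k <- sample(2:6, 1)
    depths <- sample(1:4, sample(1:3, 1), replace = TRUE)
    spec <- denseNetSpec("rand", 64L, k, as.integer(depths),
                         sample(1:4, 1), theta = runif(1, 0.3, 1))
    led <- channelLedger(spec)
    expect_equal(unname(led), recurrenceOracle(spec))
    model <- buildNetwork(spec, rngSeed = r)
    nStage <- length(spec@stages)
    expect_equal(nrow(model@params[[nStage]]$W),
                 unname(led[nStage - 1L]))   # classifier consumes GAP depth
  }
})

test_that("spatial traces follow the stride arithmetic down to 8 x 8 and GAP", {
  t512 <- unname(spatialTrace(denseNet512Spec()))
  expect_equal(t512, c(256L, 128L, 128L, 64L, 64L, 32L, 32L, 16L, 16L, 8L,
                       8L, 1L, 1L))
  t1024 <- unname(spatialTrace(denseNet1024Spec()))
  expect_equal(t1024, c(512L, 256L, 256L, 128L, 128L, 64L, 64L, 32L, 32L,
                        16L, 16L, 8L, 8L, 1L, 1L))

  # a stride-1 stem with no pooling keeps the side constant
  flat <- new("NetworkSpec", name = "flat", inputSide = 32L,
              inputChannels = 1L, k = 2L, theta = 0.5,
              stages = list(list(type = "DBa", h = 7L, w = 7L, s = 1L,
                                 f = 4L, d = 1L, variant = "basic"),
                            list(type = "GAP"),
                            list(type = "C", units = 6L)))
  expect_equal(unname(spatialTrace(flat)), c(32L, 1L, 1L))

  # underflow / odd transition side errors carry the stage trace
  bad <- denseNetSpec("bad", 16L, 2L, c(1L, 1L, 1L), 1L)
  expect_error(spatialTrace(bad), "trace")
  expect_error(buildNetwork(bad), "trace")
})

test_that("dense concatenation follows the feature-map arithmetic", {
  # toy block with per-layer filter counts 3, 5, 2 on a depth-1 input:
  # layer 3 consumes 1 + 3 + 5 = 9 maps, the block emits 1 + 3 + 5 + 2 = 11
  set.seed(21)
  x <- array(runif(8 * 8), c(8, 8, 1, 1))
  acc <- x
  for (f in c(3L, 5L, 2L)) {
    cfg <- list(h = 3L, w = 3L, s = 1L, f = f, variant = "basic")
    ini <- myoStage:::initComposite(cfg, dim(acc)[3])
    if (f == 2L) expect_equal(dim(acc)[3], 9L)
    out <- myoStage:::compositeForward(acc, ini$p, ini$st, cfg, train = TRUE)
    acc <- myoStage:::bindChannels(acc, out$y)
  }
  expect_equal(dim(acc)[3], 11L)

  # DBb(d = 6, f = 20) on a depth-40 input emits 160 maps
  cfg <- list(type = "DBb", h = 3L, w = 3L, s = 1L, f = 20L, d = 6L,
              variant = "bottleneck")
  spec40 <- denseNetSpec("w", 64L, 20L, c(6L), 1L)
  model <- buildNetwork(spec40, 1)
  xin <- array(runif(4 * 4 * 40 * 2), c(4, 4, 40, 2))
  fw <- myoStage:::denseBlockForward(xin, model@params[[3]],
                                     model@state[[3]], cfg, train = TRUE)
  expect_equal(dim(fw$y), c(4L, 4L, 160L, 2L))
})

test_that("transition layers compress by floor(theta m) and average pooling preserves constants", {
  expect_equal(floor(0.5 * 160), 80)
  x <- array(0.7, c(6, 6, 3, 2))
  y <- myoStage:::avgpool2_forward_cpp(x)
  expect_equal(dim(y), c(3L, 3L, 3L, 2L))
  expect_equal(max(abs(y - 0.7)), 0)

  # identity 1 x 1 convolution keeps a constant field constant
  W <- array(0, c(1, 1, 3, 3)); for (c in 1:3) W[1, 1, c, c] <- 1
  h <- myoStage:::conv2d_forward_cpp(x, W, rep(0, 3), 1L, 0L)
  expect_equal(max(abs(h - 0.7)), 0)
})

test_that("compiled convolution agrees with a direct triple-loop oracle", {
  set.seed(22)
  x <- array(runif(9 * 9 * 2 * 2), c(9, 9, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  b <- rnorm(4)
  for (cfg in list(c(1L, 1L), c(2L, 1L), c(2L, 3L))) {
    y <- myoStage:::conv2d_forward_cpp(x, w, b, cfg[1], cfg[2])
    for (n in 1:2)
      expect_equal(y[, , , n], convOracle(x[, , , n], w, b,
                                          cfg[1], cfg[2]), tolerance = 1e-12)
  }
})

test_that("softmax head yields a probability vector for arbitrary magnitudes", {
  z <- matrix(c(1e8, -1e8, 0, 3, -3, 700,
                -745, 745, 0.1, 0, 0, 0), 6, 2)
  p <- myoStage:::softmaxCols(z)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(colSums(p), c(1, 1), tolerance = 1e-12)

  set.seed(23)
  spec <- denseNetSpec("micro", 32L, 2L, c(1L), 1L)
  m <- buildNetwork(spec, 1)
  pr <- predictScores(m, array(runif(32 * 32 * 4), c(32, 32, 1, 4)))
  expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-5)
  expect_true(all(pr >= 0))
  expect_error(predictScores(m, matrix(0, 16, 16)), "side")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(24)
  spec <- denseNetSpec("micro", 32L, 2L, c(1L), 1L)
  m <- buildNetwork(spec, 1)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  labels <- c(0L, 3L, 5L)
  lossAt <- function(model) {
    f <- myoStage:::networkForward(model, x, train = TRUE)
    myoStage:::crossEntropy(f$probs, labels)
  }
  fw <- myoStage:::networkForward(m, x, train = TRUE)
  dz <- fw$probs
  dz[cbind(labels + 1L, 1:3)] <- dz[cbind(labels + 1L, 1:3)] - 1
  gr <- myoStage:::networkBackward(m, fw$caches, dz / 3)
  eps <- 1e-5
  # one parameter from each layer family: stem conv, bottleneck BN + convs,
  # transition conv, classifier
  probe <- list(
    list(p = function(m) m@params[[1]]$layers[[1]]$conv$W,
         g = function(g) g[[1]]$layers[[1]]$conv$W,
         set = function(m, v) { m@params[[1]]$layers[[1]]$conv$W[10] <- v; m },
         i = 10),
    list(p = function(m) m@params[[3]]$layers[[1]]$bn1$gamma,
         g = function(g) g[[3]]$layers[[1]]$bn1$gamma,
         set = function(m, v) { m@params[[3]]$layers[[1]]$bn1$gamma[1] <- v; m },
         i = 1),
    list(p = function(m) m@params[[3]]$layers[[1]]$conv2$W,
         g = function(g) g[[3]]$layers[[1]]$conv2$W,
         set = function(m, v) { m@params[[3]]$layers[[1]]$conv2$W[5] <- v; m },
         i = 5),
    list(p = function(m) m@params[[4]]$conv$W,
         g = function(g) g[[4]]$conv$W,
         set = function(m, v) { m@params[[4]]$conv$W[2] <- v; m },
         i = 2),
    list(p = function(m) m@params[[7]]$W,
         g = function(g) g[[7]]$W,
         set = function(m, v) { m@params[[7]]$W[4] <- v; m },
         i = 4))
  for (pb in probe) {
    base <- pb$p(m)[pb$i]
    num <- (lossAt(pb$set(m, base + eps)) - lossAt(pb$set(m, base - eps))) /
      (2 * eps)
    expect_equal(pb$g(gr)[pb$i], num, tolerance = 1e-5)
  }
})

test_that("evaluation-mode inference is deterministic for repeated samples", {
  set.seed(25)
  spec <- denseNetSpec("micro", 32L, 2L, c(1L), 1L)
  m <- buildNetwork(spec, 1)
  img <- matrix(runif(32 * 32), 32, 32)
  x <- array(c(img, img), c(32, 32, 1, 2))
  pr <- predictScores(m, x)
  expect_identical(pr[1, ], pr[2, ])
})
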