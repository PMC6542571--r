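# Dataset builder: balancing, augmentation techniques A and B, resizing,
# rotation geometry.

test_that("random under-sampling balances classes and reports remainders", {
  set.seed(1)
  pool <- standinPool(c(0L, 18L, 23L, 22L, 22L, 26L))
  bal <- balanceByUndersampling(pool, 15, rngSeed = 4)
  expect_length(bal$selected, 75)
  selLab <- table(vapply(bal$selected, classLabel, 0L))
  expect_true(all(selLab == 15))
  remLab <- table(factor(vapply(bal$remainder, classLabel, 0L), levels = 1:5))
  expect_equal(unname(as.integer(remLab)), c(3L, 8L, 7L, 7L, 11L))

  # exact-size pool leaves nothing behind
  even <- standinPool(c(0L, 2L, 2L, 2L, 2L, 2L))
  balEven <- balanceByUndersampling(even, 2, rngSeed = 1)
  expect_length(balEven$remainder, 0)

  short <- standinPool(c(0L, 1L, 5L, 5L, 5L, 5L))
  expect_error(balanceByUndersampling(short, 3, rngSeed = 1), "class 1")
})

test_that("selection frequencies match the hypergeometric inclusion probability", {
  set.seed(2)
  pool <- standinPool(c(0L, 18L, 23L, 22L, 22L, 26L), side = 8L)
  target <- sourceId(pool[[1]])     # a fixed class-1 member
  hits <- 0L
  n <- 1000L
  for (s in seq_len(n)) {
    bal <- balanceByUndersampling(pool, 15, rngSeed = s)
    ids <- vapply(bal$selected, sourceId, "")
    if (target %in% ids) hits <- hits + 1L
  }
  expect_equal(hits / n, 15 / 18, tolerance = 0.05 / (15 / 18))
})

test_that("the default rotation plan has 144 distinct angles, 0 and 2pi never both", {
  plan <- augmentationPlanA()
  expect_length(plan$angles, 144)
  expect_false(anyDuplicated(round(plan$angles %% (2 * pi), 10)) > 0)
  expect_true(0 %in% plan$angles)
  expect_false(any(abs(plan$angles - 2 * pi) < 1e-9))
  expect_equal(length(plan$flips) * length(plan$angles), 288)
})

test_that("technique A produces the exact sample counts and unique provenance", {
  set.seed(3)
  train <- standinPool(rep(15L, 6), side = 64L)     # 90 balanced sources
  manifest <- augmentTechniqueA(train, name = "T-64-A")
  expect_equal(length(manifest), 25920L)

  s <- manifestSamples(manifest)
  expect_false(anyDuplicated(s[, c("source_id", "flip", "angle_rad")]) > 0)

  # label conservation: histogram = 288 x source histogram
  expect_equal(unname(classCounts(manifest)), rep(15L * 288L, 6))

  evalPool <- standinPool(c(9L, 3L, 8L, 7L, 7L, 11L) + c(0L, 0L, 0L, 0L, 0L, 1L),
                          side = 64L)   # 46 evaluation sources
  expect_length(evalPool, 46)
  expect_equal(length(augmentTechniqueA(evalPool)), 13248L)

  mixed <- c(standinPool(c(1L), side = 64L), standinPool(c(1L), side = 32L))
  expect_error(augmentTechniqueA(mixed), "mixed")
})

test_that("identity rotation reproduces the source pixel-for-pixel", {
  set.seed(4)
  src <- standinSource("one", 3L)
  plan <- augmentationPlanA(deltaPhi = 2 * pi)    # single angle 0
  manifest <- augmentTechniqueA(list(src), plan)
  expect_equal(length(manifest), 2L)
  s <- manifestSamples(manifest)
  unflipped <- which(!s$flip)
  expect_identical(materializeSample(manifest, unflipped), pixels(src))
  flipped <- which(s$flip)
  expect_identical(materializeSample(manifest, flipped),
                   pixels(src)[, 64:1])
})

test_that("rotation round-trips on the central disc and fills corners with background", {
  # smooth test image: interpolation error must vanish on the central disc
  n <- 101
  g <- outer(1:n, 1:n, function(i, j)
    0.5 + 0.3 * sin(i / 8) * cos(j / 11) + 0.002 * i)
  ang <- 0.7
  back <- rotateImage(rotateImage(g, ang), -ang)
  d <- sqrt(outer((1:n - 51)^2, (1:n - 51)^2, "+"))
  disc <- d < 30
  expect_lt(max(abs(back[disc] - g[disc])), 0.02)
  expect_lt(mean(abs(back[disc] - g[disc])), 0.005)

  const <- matrix(0.4, 64, 64)
  rot <- rotateImage(const, 0.5)
  expect_equal(max(abs(rot - 0.4)), 0, tolerance = 1e-12)
})

test_that("technique B triples the set and preserves the target object", {
  set.seed(6)
  sources <- standinPool(c(15L, rep(15L, 5)), side = 64L)   # 15 class0 + 75
  extra0 <- standinPool(c(30L), side = 64L)
  for (i in seq_along(extra0))
    extra0[[i]]@sourceId <- paste0("x", sourceId(extra0[[i]]))
  distr <- generateDistractors(6, 64 * 8, rngSeed = 1)      # small rasters
  distr <- lapply(distr, function(d) list(
    pixels = d$pixels[1:8, 1:8, drop = FALSE],
    mask = matrix(TRUE, 8, 8)))
  ext <- extendTechniqueB(sources, distr, extra0, rngSeed = 2)
  expect_length(ext, 90 + 150 + 30)                          # 270 sources
  manifest <- augmentTechniqueA(ext, name = "T-64-B")
  expect_equal(length(manifest), 77760L)
  expect_equal(length(manifest) /
                 length(augmentTechniqueA(sources)), 3)

  # the composited target equals the original cut-out under its mask
  plain <- Filter(function(s) variantTag(s) == "modified_plain", ext)
  expect_length(plain, 75)
  p1 <- plain[[1]]
  orig <- sources[[which(vapply(sources, sourceId, "") ==
                           sub("_plain$", "", sourceId(p1)))]]
  expect_equal(sort(pixels(p1)[objectMask(p1)]),
               sort(pixels(orig)[objectMask(orig)]))

  withD <- Filter(function(s) variantTag(s) == "modified_distractor", ext)
  expect_length(withD, 75)
  d1 <- withD[[1]]
  expect_equal(sort(pixels(d1)[objectMask(d1)]),
               sort(pixels(orig)[objectMask(orig)]))

  # reproducibility and mask prerequisites
  ext2 <- extendTechniqueB(sources, distr, extra0, rngSeed = 2)
  expect_identical(pixels(ext2[[91]]), pixels(ext[[91]]))
  bad <- sources
  bad[[16]]@objectMask <- matrix(FALSE, 64, 64)
  bad[[16]]@classLabel <- 1L
  expect_error(suppressWarnings(extendTechniqueB(bad, distr, list(),
                                                 rngSeed = 1)), "mask")
})

test_that("bicubic down-sampling halves sides, doubles pixel size, keeps constants", {
  src <- SourceImage(matrix(0.37, 128, 128), 0L, 58, sourceId = "const")
  out <- resizeSources(list(src), 64L)[[1]]
  expect_equal(dim(pixels(out)), c(64L, 64L))
  expect_equal(pixelSize(out), 116)
  expect_equal(max(abs(pixels(out) - 0.37)), 0, tolerance = 1e-9)

  expect_error(resizeSources(list(src), 256L), "up-sampling")
  expect_error(resizeSources(list(src), 48L), "divide")
})

test_that("down-sampling halves the measured stripe period", {
  img <- generateStageImage(5, 512, 100, rngSeed = 8, sarcomereSpacingUm = 2.0)
  half <- resizeSources(list(img), 256L)[[1]]
  p0 <- stripePeriod(img)$period
  p1 <- stripePeriod(half, periodBand = c(3, 40))$period
  expect_equal(p1, p0 / 2, tolerance = 0.05)
})
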