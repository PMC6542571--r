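# Evaluation: macro metrics against a brute-force oracle, neighbour-error
# partition, the class probability graph and its bar table.

test_that("perfect prediction scores 100 on all three measures", {
  cm <- confusionSummary(rep(0:5, each = 4), rep(0:5, each = 4))
  met <- computeMetrics(cm)
  expect_equal(met$avgPerClassAccuracy, 100)
  expect_equal(met$macroPrecision, 100)
  expect_equal(met$macroRecall, 100)
  expect_equal(unname(neighbourErrorSummary(cm)),
               c(24L, 0L, 0L))
})

test_that("a two-class toy confusion reproduces hand-computed fractions", {
  # class 1: TP = 3, FN = 1, FP = 2, TN = 4; class 0 complementary
  cm <- matrix(0L, 6, 6)
  cm[1, 1] <- 4L; cm[1, 2] <- 2L; cm[2, 1] <- 1L; cm[2, 2] <- 3L
  met <- computeMetrics(cm)
  pc <- met$perClass
  expect_equal(pc$accuracy[2], 7 / 10)
  expect_equal(pc$precision[2], 3 / 5)
  expect_equal(pc$recall[2], 3 / 4)
  expect_equal(pc$accuracy[1], 7 / 10)
  # empty classes contribute accuracy 1, precision 0, recall 0
  expect_equal(met$avgPerClassAccuracy, 100 * (0.7 + 0.7 + 4) / 6)
  expect_equal(met$macroPrecision, 100 * (4 / 5 + 3 / 5) / 6)
  expect_equal(met$macroRecall, 100 * (4 / 6 + 3 / 4) / 6)
  expect_error(computeMetrics(matrix(0L, 6, 6)), "empty")
})

test_that("metrics agree with the brute-force oracle on 500 random grids", {
  set.seed(30)
  for (r in 1:500) {
    n <- sample(10:200, 1)
    true <- sample(0:5, n, replace = TRUE)
    pred <- sample(0:5, n, replace = TRUE)
    met <- computeMetrics(confusionSummary(true, pred))
    ora <- metricsOracle(true, pred)
    expect_equal(met$avgPerClassAccuracy, ora$acc, tolerance = 1e-12)
    expect_equal(met$macroPrecision, ora$prec, tolerance = 1e-12)
    expect_equal(met$macroRecall, ora$rec, tolerance = 1e-12)
  }
})

test_that("uniform random prediction attains chance-level macro recall", {
  set.seed(31)
  true <- rep(0:5, each = 2000)
  pred <- sample(0:5, length(true), replace = TRUE)
  met <- computeMetrics(confusionSummary(true, pred))
  expect_equal(met$macroRecall, 100 / 6, tolerance = 0.1)
})

test_that("metrics are invariant to sample order", {
  set.seed(32)
  true <- sample(0:5, 300, replace = TRUE)
  pred <- sample(0:5, 300, replace = TRUE)
  perm <- sample(300)
  expect_identical(confusionSummary(true, pred),
                   confusionSummary(true[perm], pred[perm]))
})

test_that("neighbour errors are adjacent stages only; class 0 is nobody's neighbour", {
  cm <- matrix(0L, 6, 6)
  cm[4, 5] <- 7L     # true 3 predicted 4: questionable neighbour error
  cm[3, 4] <- 2L     # true 2 predicted 3: neighbour
  cm[6, 1] <- 3L     # true 5 predicted 0: distant
  cm[2, 1] <- 4L     # true 1 predicted 0: distant
  cm[1, 1] <- 5L
  ne <- neighbourErrorSummary(cm)
  expect_equal(unname(ne), c(5L, 9L, 7L))
  expect_equal(sum(ne), sum(cm))
})

# synthetic scored table for graph tests
makeScored <- function(nSources = 6, nAngles = 24, flips = FALSE, seed = 40) {
  set.seed(seed)
  angles <- (seq_len(nAngles) - 1) * 2 * pi / 23
  rows <- expand.grid(angle_rad = angles,
                      flip = if (flips) c(FALSE, TRUE) else FALSE,
                      src = seq_len(nSources))
  probs <- matrix(stats::rexp(nrow(rows) * 6), ncol = 6)
  probs <- probs / rowSums(probs)
  colnames(probs) <- paste0("class", 0:5)
  cbind(data.frame(
    sample_id = sprintf("s%d_f%d_a%.4f", rows$src, rows$flip, rows$angle_rad),
    source_id = sprintf("src%d", rows$src),
    class_label = (rows$src - 1L) %% 6L,
    flip = rows$flip,
    angle_rad = rows$angle_rad), as.data.frame(probs))
}

test_that("six sources with 24 rotations yield 144 bars whose segments sum to the bar height", {
  scored <- makeScored(6, 24)
  g <- classProbabilityGraph(scored, barHeight = 1)
  expect_equal(nrow(g$barTable), 144L)
  sums <- unname(rowSums(g$barTable[, paste0("h", 0:5)]))
  expect_equal(sums, rep(1, 144), tolerance = 1e-9)
  expect_s3_class(g$plot, "ggplot")

  # one-hot scores paint the whole bar in one class colour segment
  one <- makeScored(1, 1)
  one[, paste0("class", 0:5)] <- c(1, 0, 0, 0, 0, 0)
  g1 <- classProbabilityGraph(one)
  expect_equal(g1$barTable$h0, 1)
  expect_equal(sum(unlist(g1$barTable[, paste0("h", 1:5)])), 0)
})

test_that("bar-table columns sum to the bar height for random score vectors", {
  scored <- makeScored(10, 25, flips = TRUE, seed = 41)
  h <- 2.5
  g <- classProbabilityGraph(scored, barHeight = h)
  expect_equal(nrow(g$barTable), nrow(scored))
  expect_equal(unname(rowSums(g$barTable[, paste0("h", 0:5)])),
               rep(h, nrow(scored)), tolerance = 1e-9)
})

test_that("the canonical layout is invariant to input shuffling", {
  scored <- makeScored(5, 12, flips = TRUE, seed = 42)
  g1 <- classProbabilityGraph(scored)
  set.seed(43)
  g2 <- classProbabilityGraph(scored[sample(nrow(scored)), ])
  o1 <- g1$barTable[order(g1$barTable$sample_id), ]
  o2 <- g2$barTable[order(g2$barTable$sample_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # flipped samples sit in the right half-columns
  nAng <- length(unique(scored$angle_rad))
  expect_true(all(g1$barTable$col[g1$barTable$flip] > nAng))
  expect_true(all(g1$barTable$col[!g1$barTable$flip] <= nAng))
})

test_that("missing provenance is an explicit error", {
  scored <- makeScored(2, 3)
  scored$angle_rad <- NULL
  expect_error(classProbabilityGraph(scored), "angle_rad")
})

test_that("scoring a manifest preserves order and the probability contract", {
  set.seed(44)
  spec <- denseNetSpec("micro", 32L, 2L, c(1L), 1L)
  m <- buildNetwork(spec, 1)
  pool <- standinPool(c(1L, 1L, 1L), side = 32L)
  manifest <- augmentTechniqueA(pool, augmentationPlanA(deltaPhi = pi))
  sc <- scoreSet(m, manifest)
  expect_equal(nrow(sc), length(manifest))
  expect_equal(sc$sample_id, manifestSamples(manifest)$sample_id)
  probs <- as.matrix(sc[, paste0("class", 0:5)])
  expect_equal(rowSums(probs), rep(1, nrow(sc)), tolerance = 1e-6)
  expect_true(all(sc$predicted %in% 0:5))

  emptyMan <- augmentTechniqueA(standinPool(c(1L), side = 32L),
                                augmentationPlanA(deltaPhi = pi))
  emptyMan@samples <- emptyMan@samples[0, ]
  expect_equal(nrow(scoreSet(m, emptyMan)), 0L)
})
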