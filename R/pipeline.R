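# End-to-end experiment: generate/balance sources, build the augmented
# manifests for both techniques, train at a configurable scale and evaluate
# on the flip/rotation evaluation manifest.

#' Generate a synthetic pool of labelled source images
#'
#' Draws \code{perStage} images of each development stage 1--5 plus
#' \code{nClass0} reject-class images cycling through the four junk kinds,
#' at the generator's native 512 px (optionally down-sampled afterwards
#' with \code{\link{resizeSources}}).
#'
#' @param perStage images per stage 1--5.
#' @param nClass0 reject-class images.
#' @param sidePx generator side (512 or 1024).
#' @param pixelSizeNm physical pixel size in nm.
#' @param rngSeed integer base seed; image i derives its own child seed.
#' @return list of \linkS4class{SourceImage}.
#' @export
generateFixtureSources <- function(perStage = 15L, nClass0 = 15L,
                                   sidePx = 512L, pixelSizeNm = 100,
                                   rngSeed = 1L) {
  pool <- list()
  kinds <- c("empty", "fragment", "out_of_focus", "dead_cell")
  i <- 0L
  for (stage in 1:5) {
    for (j in seq_len(perStage)) {
      i <- i + 1L
      img <- generateStageImage(stage, sidePx, pixelSizeNm,
                                rngSeed = childSeed(rngSeed, i))
      img@sourceId <- sprintf("st%d_%02d", stage, j)
      pool[[length(pool) + 1L]] <- img
    }
  }
  for (j in seq_len(nClass0)) {
    i <- i + 1L
    img <- generateClass0Image(kinds[(j - 1L) %% 4L + 1L], sidePx,
                               pixelSizeNm, rngSeed = childSeed(rngSeed, i))
    img@sourceId <- sprintf("c0_%02d", j)
    pool[[length(pool) + 1L]] <- img
  }
  pool
}

#' Experiment configuration
#'
#' @param spec a \linkS4class{NetworkSpec} (default: the tiny desk-scale
#'   preset; the full 512/1024 presets require GPU-scale resources).
#' @param technique augmentation technique, \code{"A"} (flip/rotation) or
#'   \code{"B"} (cut-out compositing extension, then A).
#' @param perClassSources balanced sources per class.
#' @param plan an \code{\link{augmentationPlanA}}; scale \code{deltaPhi} up
#'   for desk-scale runs.
#' @param evalPlan plan for the evaluation manifest.
#' @param epochsA epochs for a technique-A-sized set; technique B uses
#'   \code{\link{equalizeEpochs}} so the total samples seen match.
#' @param batchSize training batch size.
#' @param alpha ADAM learning rate passed to \code{\link{trainingConfig}}.
#' @param pixelSizeNm acquisition pixel size in nm for generated fixtures
#'   (default: 100, the middle of the supported 58--116 range).
#' @param datasetSeed,trainSeed integer seeds for data generation/selection
#'   and for weight initialisation/shuffling.
#' @param dryRun if TRUE, build manifests and audit ledgers only, skip
#'   training.
#' @return list of settings for \code{\link{runExperiment}}.
#' @export
experimentConfig <- function(spec = tinyDenseNetSpec(), technique = c("A", "B"),
                             perClassSources = 15L,
                             plan = augmentationPlanA(),
                             evalPlan = plan,
                             epochsA = 15L, batchSize = 9L,
                             alpha = 5e-4, pixelSizeNm = 100,
                             datasetSeed = 1L, trainSeed = 1L,
                             dryRun = FALSE) {
  list(spec = spec, technique = match.arg(technique),
       perClassSources = as.integer(perClassSources), plan = plan,
       evalPlan = evalPlan, epochsA = as.integer(epochsA),
       batchSize = as.integer(batchSize), alpha = alpha,
       pixelSizeNm = pixelSizeNm,
       datasetSeed = as.integer(datasetSeed),
       trainSeed = as.integer(trainSeed), dryRun = isTRUE(dryRun))
}

#' Run a staged-classification experiment end to end
#'
#' Generates a synthetic source pool (or uses the one supplied), balances
#' it by random under-sampling, builds the training manifest for the chosen
#' augmentation technique and the flip/rotation evaluation manifest from
#' the remainder, trains the network, and evaluates. Evaluation always uses
#' the technique-A manifest regardless of the training technique, keeping
#' results comparable. Total samples seen are equalized across techniques
#' via \code{\link{equalizeEpochs}}.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param pool optional list of \linkS4class{SourceImage} to use instead of
#'   generated fixtures (sides must match the network input).
#' @param verbose print progress.
#' @return list with \code{trainManifest}, \code{evalManifest},
#'   \code{channelLedger}, \code{spatialTrace}, and unless dry-run:
#'   \code{model}, \code{trainingLedger}, \code{metrics}, \code{confusion},
#'   \code{scored}, \code{graph}, \code{provenance}.
#' @export
runExperiment <- function(config = experimentConfig(), pool = NULL,
                          verbose = FALSE) {
  spec <- config$spec
  side <- spec@inputSide
  if (is.null(pool)) {
    if (verbose) message("generating synthetic source pool ...")
    genSide <- 512L
    # a slight surplus over the balanced count leaves evaluation sources
    surplus <- max(2L, ceiling(config$perClassSources / 3))
    pool <- generateFixtureSources(config$perClassSources + surplus,
                                   config$perClassSources + surplus,
                                   sidePx = genSide,
                                   pixelSizeNm = config$pixelSizeNm,
                                   rngSeed = config$datasetSeed)
    if (genSide != side) pool <- resizeSources(pool, side)
  }
  labels <- vapply(pool, classLabel, 0L)
  bal <- balanceByUndersampling(pool[labels > 0], config$perClassSources,
                                rngSeed = config$datasetSeed)
  class0 <- pool[labels == 0]
  nTrain0 <- min(config$perClassSources, length(class0))
  trainSources <- c(bal$selected, class0[seq_len(nTrain0)])
  evalSources <- c(bal$remainder, class0[seq_len(length(class0)) > nTrain0])

  if (config$technique == "B") {
    distr <- generateDistractors(12L, side,
                                 rngSeed = childSeed(config$datasetSeed, 77))
    nExtra0 <- 2L * nTrain0
    extra0 <- lapply(seq_len(nExtra0), function(j) {
      kinds <- c("empty", "fragment", "out_of_focus", "dead_cell")
      img <- generateClass0Image(kinds[(j - 1L) %% 4L + 1L], 512L,
                                 config$pixelSizeNm,
                                 rngSeed = childSeed(config$datasetSeed,
                                                    1000L + j))
      img@sourceId <- sprintf("c0x_%02d", j)
      img
    })
    if (side != 512L) extra0 <- resizeSources(extra0, side)
    trainSources <- extendTechniqueB(trainSources, distr, extra0,
                                     rngSeed = childSeed(config$datasetSeed,
                                                         88))
  }
  trainManifest <- augmentTechniqueA(trainSources, config$plan,
                                     name = sprintf("T-%d-%s", side,
                                                    config$technique))
  evalManifest <- augmentTechniqueA(evalSources, config$evalPlan,
                                    name = sprintf("E-%d-A", side))

  out <- list(trainManifest = trainManifest, evalManifest = evalManifest,
              channelLedger = channelLedger(spec),
              spatialTrace = spatialTrace(spec))
  if (config$dryRun) return(out)

  # the size technique A alone would have produced, for epoch equalization
  sizeA <- (length(bal$selected) + nTrain0) * length(config$plan$angles) *
    length(config$plan$flips)
  epochs <- if (config$technique == "A") config$epochsA else
    equalizeEpochs(sizeA, length(trainManifest), config$epochsA)

  if (verbose) message("training for ", epochs, " epochs on ",
                       length(trainManifest), " samples ...")
  model <- buildNetwork(spec, rngSeed = config$trainSeed)
  tc <- trainingConfig(alpha = config$alpha, batchSize = config$batchSize,
                       epochs = epochs, rngSeed = config$trainSeed)
  tr <- trainNetwork(model, trainManifest, tc, verbose = verbose)

  if (verbose) message("scoring ", length(evalManifest), " evaluation samples ...")
  scored <- scoreSet(tr$model, evalManifest)
  confusion <- confusionSummary(scored$class_label, scored$predicted)
  metrics <- computeMetrics(confusion)
  graph <- classProbabilityGraph(scored)

  out$model <- tr$model
  out$trainingLedger <- tr$ledger
  out$scored <- scored
  out$confusion <- confusion
  out$metrics <- metrics
  out$neighbourErrors <- neighbourErrorSummary(confusion)
  out$graph <- graph
  out$provenance <- list(
    spec = spec@name, inputSide = side, technique = config$technique,
    perClassSources = config$perClassSources,
    deltaPhi = config$plan$deltaPhi, epochs = epochs,
    batchSize = config$batchSize, datasetSeed = config$datasetSeed,
    trainSeed = config$trainSeed,
    packageVersion = as.character(utils::packageVersion("myoStage")))
  out
}
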