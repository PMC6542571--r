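# Training: ADAM on cross-entropy over shuffled complete epochs, with a
# ledger guaranteeing the samples-seen bookkeeping that makes runs on
# differently sized augmented sets comparable.

#' Training configuration
#'
#' Defaults follow the reference regime: ADAM with learning rate
#' \code{5e-4}, first/second moment decays 0.95 and 0.999, cross-entropy
#' loss. Batch sizes of 9 (512 px input) and 3 (1024 px input) were dictated
#' by GPU memory at full scale; desk-scale runs may use larger batches.
#'
#' @param alpha learning rate.
#' @param beta1,beta2 ADAM exponential decay rates, each in (0, 1).
#' @param batchSize samples per batch.
#' @param epochs complete passes over the training manifest.
#' @param rngSeed integer seed controlling shuffling.
#' @return list of validated settings.
#' @export
trainingConfig <- function(alpha = 5e-4, beta1 = 0.95, beta2 = 0.999,
                           batchSize = 9L, epochs = 15L, rngSeed = 1L) {
  stopifnot(alpha > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batchSize >= 1, epochs >= 0)
  list(alpha = alpha, beta1 = beta1, beta2 = beta2,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       rngSeed = as.integer(rngSeed))
}

#' Equalize total samples seen across differently sized training sets
#'
#' Training runs on sets of different sizes are comparable when the same
#' total number of samples (iterations) is processed: for example 15 epochs
#' on a 25,920-sample set equals 5 epochs on a 77,760-sample set.
#'
#' @param sizeA,sizeB manifest sizes.
#' @param epochsA epochs used on the first set.
#' @return epochs for the second set such that
#'   \code{epochsB * sizeB == epochsA * sizeA}.
#' @export
equalizeEpochs <- function(sizeA, sizeB, epochsA) {
  total <- as.numeric(epochsA) * sizeA
  epochsB <- total / sizeB
  if (epochsB != round(epochsB))
    stop(sprintf(
      "%d epochs x %d samples = %.0f is not divisible by %d; set epochs explicitly",
      epochsA, sizeA, total, sizeB))
  as.integer(epochsB)
}

# Recursive ADAM update over nested parameter/gradient lists (stage lists
# are positional, layer parameter lists are named; both are walked).
adamStep <- function(params, grads, opt, cfg, t) {
  if (is.list(params)) {
    keys <- if (is.null(names(params))) seq_along(params) else names(params)
    for (nm in keys) {
      g <- if (is.character(nm) || length(grads) >= nm) grads[[nm]] else NULL
      if (is.null(g)) next
      o <- if (is.character(nm) || length(opt) >= nm) opt[[nm]] else NULL
      res <- adamStep(params[[nm]], g, if (is.null(o)) list() else o, cfg, t)
      params[[nm]] <- res$p
      opt[[nm]] <- res$o
    }
    return(list(p = params, o = opt))
  }
  if (is.null(opt$m)) { opt$m <- params * 0; opt$v <- params * 0 }
  opt$m <- cfg$beta1 * opt$m + (1 - cfg$beta1) * grads
  opt$v <- cfg$beta2 * opt$v + (1 - cfg$beta2) * grads^2
  mh <- opt$m / (1 - cfg$beta1^t)
  vh <- opt$v / (1 - cfg$beta2^t)
  list(p = params - cfg$alpha * mh / (sqrt(vh) + 1e-8), o = opt)
}

# Render the whole manifest into an (H, W, 1, N) array, each image scaled
# to [0, 1] by its maximum (the network's expected input range).
materializeAll <- function(manifest) {
  n <- length(manifest)
  side <- manifest@sidePx
  x <- array(0, c(side, side, 1L, n))
  for (i in seq_len(n)) {
    px <- materializeSample(manifest, i)
    mx <- max(px)
    x[, , 1L, i] <- if (mx > 0) px / mx else px
  }
  x
}

#' Train a DenseNet on a dataset manifest
#'
#' Minimises cross-entropy with ADAM. Batches are drawn from a queue of all
#' samples reshuffled at the start of every epoch, so each sample is seen
#' exactly \code{epochs} times; a final short batch is used as-is. Returns
#' the trained model and a ledger: samples seen, batches run, and per-epoch
#' mean loss and training accuracy (both computed from the optimisation
#' forward passes, i.e. with batch statistics, as training frameworks
#' conventionally log them).
#'
#' @param model a \linkS4class{DenseNetModel}.
#' @param manifest a \linkS4class{DatasetManifest} whose side matches the
#'   model input, or a list \code{list(x = array, labels = integer)} of
#'   pre-materialised samples.
#' @param config a \code{\link{trainingConfig}}.
#' @param verbose print per-epoch mean loss.
#' @return list with \code{model} and \code{ledger}.
#' @export
trainNetwork <- function(model, manifest, config = trainingConfig(),
                         verbose = FALSE) {
  if (is(manifest, "DatasetManifest")) {
    if (length(manifest) == 0) stop("empty manifest")
    if (manifest@sidePx != model@spec@inputSide)
      stop("manifest side ", manifest@sidePx,
           " does not match network input side ", model@spec@inputSide)
    x <- materializeAll(manifest)
    labels <- as.integer(manifest@samples$class_label)
  } else {
    x <- manifest$x
    labels <- as.integer(manifest$labels)
    if (dim(x)[4] == 0) stop("empty manifest")
    if (dim(x)[1] != model@spec@inputSide)
      stop("image side does not match network input side")
  }
  n <- length(labels)
  ledger <- list(samplesSeen = 0L, batchesRun = 0L, epochLoss = numeric(0),
                 epochAccuracy = numeric(0))
  if (config$epochs == 0L)
    return(list(model = model, ledger = ledger))

  params <- model@params
  state <- model@state
  opt <- model@opt
  t <- if (is.null(attr(opt, "t"))) 0L else attr(opt, "t")
  modelEnv <- model
  withSeed(config$rngSeed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      nCorrect <- 0L
      for (start in seq(1L, n, by = config$batchSize)) {
        sel <- ord[start:min(start + config$batchSize - 1L, n)]
        xb <- x[, , , sel, drop = FALSE]
        yb <- labels[sel]
        modelEnv@params <- params
        modelEnv@state <- state
        fw <- networkForward(modelEnv, xb, train = TRUE)
        state <- fw$state
        losses <- c(losses, crossEntropy(fw$probs, yb))
        nCorrect <- nCorrect + sum(max.col(t(fw$probs)) - 1L == yb)
        dz <- fw$probs
        dz[cbind(yb + 1L, seq_along(yb))] <-
          dz[cbind(yb + 1L, seq_along(yb))] - 1
        dz <- dz / length(yb)
        grads <- networkBackward(modelEnv, fw$caches, dz)
        t <- t + 1L
        res <- adamStep(params, grads, opt, config, t)
        params <- res$p
        opt <- res$o
        ledger$batchesRun <- ledger$batchesRun + 1L
        ledger$samplesSeen <- ledger$samplesSeen + length(yb)
      }
      ledger$epochLoss <- c(ledger$epochLoss, mean(losses))
      ledger$epochAccuracy <- c(ledger$epochAccuracy, nCorrect / n)
      if (verbose)
        message(sprintf("epoch %d/%d  mean loss %.4f  accuracy %.3f",
                        ep, config$epochs, mean(losses), nCorrect / n))
    }
  })
  attr(opt, "t") <- t
  modelEnv@params <- params
  modelEnv@state <- state
  modelEnv@opt <- opt
  list(model = modelEnv, ledger = ledger)
}
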