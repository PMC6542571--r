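# Dataset assembly: class balancing by random under-sampling, the two
# non-destructive augmentation techniques, bicubic down-sampling, and
# on-demand sample materialisation.

#' Class-balanced source selection by random under-sampling
#'
#' Draws exactly \code{perClass} images of each class 1--5 uniformly at
#' random from the pool; everything unselected (including any class-0
#' images in the pool) forms the remainder, conventionally used as
#' evaluation sources.
#'
#' @param pool list of \linkS4class{SourceImage}.
#' @param perClass images to keep per class 1--5.
#' @param rngSeed integer seed; the draw is deterministic under it.
#' @return list with elements \code{selected} and \code{remainder}.
#' @examples
#' pool <- lapply(1:6, function(i)
#'   SourceImage(matrix(0.1, 32, 32), classLabel = (i - 1) %% 5 + 1, 116,
#'               objectMask = matrix(TRUE, 32, 32),
#'               sourceId = paste0("s", i)))
#' sel <- balanceByUndersampling(pool, perClass = 1, rngSeed = 1)
#' @export
balanceByUndersampling <- function(pool, perClass, rngSeed = 1L) {
  labels <- vapply(pool, classLabel, 0L)
  for (cl in 1:5) {
    if (sum(labels == cl) < perClass)
      stop(sprintf("class %d has only %d images, need %d", cl,
                   sum(labels == cl), perClass))
  }
  withSeed(rngSeed, {
    sel <- integer(0)
    for (cl in 1:5) {
      members <- which(labels == cl)
      sel <- c(sel, sample(members, perClass))
    }
    list(selected = pool[sort(sel)], remainder = pool[-sort(sel)])
  })
}

#' Rotation/flip augmentation plan (technique A)
#'
#' The default plan pairs the horizontal flip with rotations at step
#' \eqn{\Delta\varphi = 2\pi/144}: 144 distinct angles
#' \eqn{i\,\Delta\varphi,\ i = 0, \dots, 143} (0 and \eqn{2\pi} coincide and
#' are never both present), giving \eqn{2 \times 144 = 288} samples per
#' source image.
#'
#' @param deltaPhi rotation step in radians.
#' @param flips character subset of \code{c("identity", "horizontal")}.
#' @return list with \code{deltaPhi}, \code{angles} and \code{flips}.
#' @export
augmentationPlanA <- function(deltaPhi = 2 * pi / 144,
                              flips = c("identity", "horizontal")) {
  if (deltaPhi <= 0 || deltaPhi > 2 * pi) stop("deltaPhi must be in (0, 2*pi]")
  nAngles <- ceiling(2 * pi / deltaPhi - 1e-9)
  angles <- (seq_len(nAngles) - 1) * deltaPhi
  flips <- match.arg(flips, c("identity", "horizontal"), several.ok = TRUE)
  list(deltaPhi = deltaPhi, angles = angles, flips = unique(flips))
}

#' Flip/rotate augmentation of a source set (technique A)
#'
#' Every source is horizontally flipped (and kept unflipped), and both
#' versions are rotated by every angle of the plan, preserving class
#' labels. Under the default plan each source yields 288 samples, so 90
#' balanced training sources give 25,920 samples and 46 evaluation sources
#' give 13,248. Samples are stored as provenance records; pixels are
#' rendered on demand by \code{\link{materializeSample}}.
#'
#' @param sources list of \linkS4class{SourceImage}, all of one side length.
#' @param plan an \code{\link{augmentationPlanA}} list.
#' @param name manifest name.
#' @return A \linkS4class{DatasetManifest}.
#' @export
augmentTechniqueA <- function(sources, plan = augmentationPlanA(),
                              name = "T-A") {
  sides <- vapply(sources, function(s) nrow(pixels(s)), 0L)
  if (length(unique(sides)) != 1) stop("sources have mixed image sizes")
  ids <- vapply(sources, sourceId, "")
  if (anyDuplicated(ids)) stop("duplicate source ids")
  flipFlag <- plan$flips == "horizontal"
  grid <- expand.grid(angle = plan$angles, flip = flipFlag,
                      src = seq_along(sources), KEEP.OUT.ATTRS = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s|f%d|a%.7f", ids[grid$src], grid$flip + 0,
                        grid$angle),
    source_id = ids[grid$src],
    class_label = vapply(sources, classLabel, 0L)[grid$src],
    flip = grid$flip,
    angle_rad = grid$angle,
    variant = vapply(sources, variantTag, "")[grid$src],
    stringsAsFactors = FALSE)
  names(sources) <- ids
  new("DatasetManifest", name = name, sidePx = sides[1],
      samples = samples, sources = sources)
}

# Paste `obj` pixels (where objMask) onto `canvas` at 1-based offset.
pasteObject <- function(canvas, obj, objMask, at) {
  h <- nrow(obj); w <- ncol(obj)
  ri <- at[1]:(at[1] + h - 1); ci <- at[2]:(at[2] + w - 1)
  sub <- canvas[ri, ci]
  sub[objMask] <- obj[objMask]
  canvas[ri, ci] <- sub
  canvas
}

#' Extend a source set with cut-out composites (technique B)
#'
#' For every class 1--5 source the masked target cell is cut out and
#' composited at a uniformly random, fully-inside position onto (i) a
#' neutral or noisy background alone (\code{modified_plain}) and (ii) the
#' same background plus randomly placed non-target distractor objects that
#' never overlap the target mask (\code{modified_distractor}). The output
#' is the originals, the two modified images per class 1--5 source, and the
#' supplied extra class-0 sources; applying technique A to it yields a set
#' three times the size of technique A on the originals.
#'
#' @param sources list of \linkS4class{SourceImage} (classes 0--5; classes
#'   1--5 must carry non-empty masks).
#' @param distractorSupply list of \code{list(pixels, mask)} distractors,
#'   e.g. from \code{\link{generateDistractors}}; recycled as needed.
#' @param extraClass0 list of additional class-0 \linkS4class{SourceImage}.
#' @param rngSeed integer seed for placement and background choices.
#' @return list of \linkS4class{SourceImage}.
#' @export
extendTechniqueB <- function(sources, distractorSupply, extraClass0 = list(),
                             rngSeed = 1L) {
  withSeed(rngSeed, {
    modified <- list()
    for (src in sources) {
      if (classLabel(src) == 0L) next
      mask <- objectMask(src)
      if (!any(mask)) stop("class 1-5 source '", sourceId(src),
                           "' has an empty object mask")
      px <- pixels(src)
      side <- nrow(px)
      rr <- range(which(rowSums(mask) > 0))
      cc <- range(which(colSums(mask) > 0))
      obj <- px[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
      om <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
      if (nrow(obj) > side || ncol(obj) > side)
        stop("target object larger than frame")
      bgLevel <- borderMedian(px)

      for (withDistractors in c(FALSE, TRUE)) {
        # neutral (flat) or noisy background, chosen per modified image
        if (stats::runif(1) < 0.5) {
          canvas <- matrix(bgLevel, side, side)
        } else {
          canvas <- matrix(pmax(stats::rnorm(side^2, bgLevel,
                                             max(bgLevel * 0.5, 0.01)), 0),
                           side, side)
        }
        at <- c(sample.int(side - nrow(obj) + 1, 1),
                sample.int(side - ncol(obj) + 1, 1))
        newMask <- matrix(FALSE, side, side)
        newMask[at[1]:(at[1] + nrow(obj) - 1),
                at[2]:(at[2] + ncol(obj) - 1)] <- om
        if (withDistractors && length(distractorSupply) > 0) {
          nd <- sample(2:6, 1)
          picks <- sample(length(distractorSupply), nd, replace = TRUE)
          for (p in picks) {
            d <- distractorSupply[[p]]
            if (nrow(d$pixels) > side || ncol(d$pixels) > side) next
            for (try in 1:50) {
              dat <- c(sample.int(side - nrow(d$pixels) + 1, 1),
                       sample.int(side - ncol(d$pixels) + 1, 1))
              foot <- matrix(FALSE, side, side)
              foot[dat[1]:(dat[1] + nrow(d$pixels) - 1),
                   dat[2]:(dat[2] + ncol(d$pixels) - 1)] <- d$mask
              if (!any(foot & newMask)) {
                canvas <- pasteObject(canvas, d$pixels, d$mask, dat)
                break
              }
            }
          }
        }
        canvas <- pasteObject(canvas, obj, om, at)
        variant <- if (withDistractors) "modified_distractor" else
          "modified_plain"
        modified[[length(modified) + 1]] <- SourceImage(
          pmax(canvas, 0), classLabel(src), pixelSize(src), newMask,
          sourceId = paste0(sourceId(src), if (withDistractors)
            "_distr" else "_plain"),
          variant = variant)
      }
    }
    c(sources, modified, extraClass0)
  })
}

#' Bicubic down-sampling of source images
#'
#' Down-samples pixels with a separable bicubic filter (Keys kernel,
#' support widened by the scale factor so the filter anti-aliases), resizes
#' masks with nearest-neighbour, and scales the physical pixel size: 1024 px
#' images at 58--116 nm/px become 512 px images at 116--232 nm/px.
#'
#' @param sources list of \linkS4class{SourceImage}.
#' @param targetSide target side in px; must divide the source side
#'   (up-sampling is refused).
#' @return list of resized \linkS4class{SourceImage}.
#' @export
resizeSources <- function(sources, targetSide) {
  lapply(sources, function(src) {
    side <- nrow(pixels(src))
    if (targetSide > side) stop("up-sampling is not supported")
    if (side %% targetSide != 0) stop("targetSide must divide the source side")
    if (targetSide == side) return(src)
    SourceImage(pmax(resampleBicubic(pixels(src), targetSide), 0),
                classLabel(src),
                pixelSize(src) * side / targetSide,
                resampleNearest(objectMask(src), targetSide),
                sourceId = sourceId(src), variant = variantTag(src))
  })
}

#' Render one augmented sample from a manifest
#'
#' Applies the recorded horizontal flip (column mirror) and then the
#' rotation about the image centre (bilinear resampling, same-size canvas,
#' exposed corners filled with the border-median background level of the
#' source).
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param i sample index (row of \code{manifestSamples(manifest)}).
#' @return numeric pixel matrix of side \code{manifest@sidePx}.
#' @export
materializeSample <- function(manifest, i) {
  rec <- manifest@samples[i, ]
  px <- pixels(manifest@sources[[rec$source_id]])
  if (rec$flip) px <- px[, ncol(px):1, drop = FALSE]
  if (rec$angle_rad != 0)
    px <- rotate_bilinear_cpp(px, rec$angle_rad, borderMedian(px))
  px
}

#' Rotate an image matrix about its centre
#'
#' Bilinear inverse-mapped rotation on a same-size canvas; exposed corners
#' take the given fill value (default: the image's border median).
#'
#' @param px numeric matrix.
#' @param angleRad rotation angle in radians.
#' @param fill background fill value.
#' @return rotated matrix of identical shape.
#' @export
rotateImage <- function(px, angleRad, fill = borderMedian(px)) {
  rotate_bilinear_cpp(px, angleRad, fill)
}

#' Horizontally flip an image matrix
#' @param px numeric matrix.
#' @return mirrored matrix.
#' @export
flipImage <- function(px) px[, ncol(px):1, drop = FALSE]

#' Write a manifest's provenance table to CSV
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @export
writeManifest <- function(manifest, path) {
  df <- manifest@samples
  df$side_px <- manifest@sidePx
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
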