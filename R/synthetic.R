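# Synthetic confocal-like cardiomyocyte images.
#
# The generator renders the raw-data intensity convention: fluorescently
# stained membrane structures (sarcolemma outline, t-tubules) are bright on
# a dark background. Stage-specific morphology follows the staging taxonomy:
#   stage 1  no membrane invaginations
#   stage 2  sparse short (~2 um) regular perpendicular invaginations at the
#            membrane and/or a few long (>10 um) tubules
#   stage 3  a web of long transverse and longitudinal tubules
#   stage 4  dense transversal system, long longitudinal tubules, devoid areas
#   stage 5  dense transversal system filling the cell except nucleus voids,
#            sparse short longitudinal structures
# Transversal tubules repeat along the cell's long axis at the sarcomere
# spacing (1.8-2.0 um); tubule diameters are 0.1-0.3 um.

MEMBRANE_LEVEL <- 1.0   # mean intensity of the sarcolemma outline
TUBULE_LEVEL <- 0.65    # mean intensity of tubule structures
BACKGROUND_LEVEL <- 0.03
PHOTON_SCALE <- 250     # photons per unit intensity per frame
FRAME_AVERAGES <- 4     # frame averaging of the emulated acquisition
READ_NOISE_SD <- 0.008

# Smooth patchy coverage field with approximate area fraction `q`,
# built from a low-frequency random cosine mixture.
coverageField <- function(dx, dy, side, q) {
  if (q >= 1) return(TRUE)
  if (q <= 0) return(FALSE)
  g <- 0
  for (j in 1:6) {
    f <- stats::runif(2, 0.5, 3) / side
    ph <- stats::runif(1, 0, 2 * pi)
    g <- g + stats::runif(1, 0.5, 1) * cos(2 * pi * (f[1] * dx + f[2] * dy) + ph)
  }
  g > stats::quantile(g, 1 - q)
}

# Render one cell. All stochastic choices must happen under the caller's
# seed. `centreFrac` shifts the cell centre (fractions of the side) and is
# used to clip fragments at the frame border.
renderCell <- function(stage, side, pixelSizeNm, spacingUm, diamUm,
                       centreFrac = NULL, uniformInterior = FALSE) {
  umToPx <- 1000 / pixelSizeNm
  a <- side * stats::runif(1, 0.40, 0.47)       # long semi-axis, px
  b <- side * stats::runif(1, 0.17, 0.24)       # short semi-axis, px
  theta <- stats::runif(1, 0, pi)
  if (is.null(centreFrac)) centreFrac <- stats::runif(2, -0.02, 0.02)
  c0 <- (side - 1) / 2 + centreFrac * side

  ix <- seq_len(side) - 1
  dxm <- matrix(rep(ix, side), side) - c0[1]          # row offset
  dym <- matrix(rep(ix, each = side), side) - c0[2]   # column offset
  u <- cos(theta) * dxm + sin(theta) * dym            # long-axis coordinate
  v <- -sin(theta) * dxm + cos(theta) * dym
  ru <- u / a; rv <- v / b
  rho <- sqrt(ru^2 + rv^2)
  psi <- atan2(rv, ru)

  # irregular boundary perturbation of the elongated silhouette
  r <- 1 + 0.05 * sin(2 * psi + stats::runif(1, 0, 2 * pi)) +
           0.035 * sin(3 * psi + stats::runif(1, 0, 2 * pi)) +
           0.02 * sin(5 * psi + stats::runif(1, 0, 2 * pi))

  membPx <- max(1.5, 0.2 * umToPx)   # ~0.2 um optical membrane width
  wm <- membPx / b
  mask <- rho <= r
  membrane <- mask & (rho > r - wm)
  interior <- rho <= (r - wm)

  tex <- matrix(0, side, side)
  if (uniformInterior) {
    tex[interior] <- 0.7              # dead cell: bright, unstructured
  } else if (stage >= 2) {
    P <- spacingUm * umToPx           # transversal stripe period, px
    sig <- pmax(0.6, diamUm * umToPx / 2)
    pos <- (u - stats::runif(1, 0, P)) %% P
    d <- pmin(pos, P - pos)
    stripes <- exp(-d^2 / (2 * sig^2))

    q <- c(0, 0.30, 0.55, 0.85, 1.0)[stage]
    keep <- coverageField(dxm, dym, side, q)
    tfield <- stripes * keep
    if (stage == 2) {
      # short perpendicular invaginations confined near the membrane
      depth <- (2 * umToPx) / b
      tfield <- tfield * (rho > r - wm - depth)
    }

    # longitudinal tubules: segments running along the long axis
    lspec <- switch(stage,
      NULL,
      list(n = 0:2, len = c(10, 18)),
      list(n = 3:6, len = c(10, 20)),
      list(n = 2:4, len = c(3, 8)),
      list(n = 2:5, len = c(2, 4)))
    nL <- if (length(lspec$n) > 1) sample(lspec$n, 1) else lspec$n
    lfield <- matrix(0, side, side)
    if (nL > 0) {
      for (i in seq_len(nL)) {
        vi <- stats::runif(1, -0.75, 0.75) * b
        ui <- stats::runif(1, -0.6, 0.6) * a
        len <- stats::runif(1, lspec$len[1], lspec$len[2]) * umToPx
        lfield <- lfield +
          exp(-(v - vi)^2 / (2 * sig^2)) * (abs(u - ui) < len / 2)
      }
    }
    tex <- pmin(1, tfield + lfield)

    if (stage == 4) {                 # areas devoid of tubules
      for (i in seq_len(sample(2:4, 1))) {
        hu <- stats::runif(1, -0.6, 0.6) * a
        hv <- stats::runif(1, -0.6, 0.6) * b
        hr <- stats::runif(1, 1.5, 3) * umToPx
        tex[((u - hu)^2 + (v - hv)^2) < hr^2] <- 0
      }
    }
    if (stage == 5) {                 # nucleus voids
      for (i in seq_len(sample(1:2, 1))) {
        hu <- stats::runif(1, -0.4, 0.4) * a
        hv <- stats::runif(1, -0.3, 0.3) * b
        ha <- stats::runif(1, 3, 5) * umToPx
        hb <- stats::runif(1, 1.5, 2.5) * umToPx
        tex[((u - hu) / ha)^2 + ((v - hv) / hb)^2 < 1] <- 0
      }
    }
    tex[!interior] <- 0
  }

  img <- BACKGROUND_LEVEL + MEMBRANE_LEVEL * membrane +
    TUBULE_LEVEL * tex + 0.02 * interior
  list(img = img, mask = mask)
}

applyShotNoise <- function(img) {
  q <- PHOTON_SCALE * FRAME_AVERAGES
  noisy <- stats::rpois(length(img), lambda = pmax(img, 0) * q) / q
  noisy <- noisy + stats::rnorm(length(img), 0, READ_NOISE_SD)
  matrix(pmax(noisy, 0), nrow(img), ncol(img))
}

checkGenArgs <- function(sidePx, pixelSizeNm) {
  if (!sidePx %in% c(512L, 1024L))
    stop("sidePx must be 512 or 1024 (down-sample afterwards with resizeSources)")
  if (pixelSizeNm < 58 || pixelSizeNm > 116)
    stop("pixelSizeNm must lie in [58, 116] for full-resolution images")
}

#' Generate a synthetic cardiomyocyte image of a given development stage
#'
#' Renders an elongated cell silhouette with irregular boundary, a bright
#' sarcolemma outline and stage-specific t-tubule texture: transversal
#' stripes perpendicular to the cell's long axis recurring at the sarcomere
#' spacing, longitudinal tubule segments, and (per stage) membrane-confined
#' invaginations, devoid areas or nucleus voids. Poisson shot noise plus
#' Gaussian read noise emulate confocal acquisition with frame averaging.
#'
#' @param stage integer development stage 1--5.
#' @param sidePx image side, 512 or 1024 px.
#' @param pixelSizeNm physical pixel size in nm, within 58--116.
#' @param rngSeed integer seed; identical seeds give bit-identical images.
#' @param sarcomereSpacingUm transversal stripe period in micrometres
#'   (default: drawn uniformly from 1.8--2.0).
#' @param tubuleDiameterUm tubule diameter in micrometres (default: drawn
#'   uniformly from 0.1--0.3).
#' @return A \linkS4class{SourceImage} with \code{classLabel = stage} and an
#'   object mask covering roughly 20--60\% of the frame.
#' @examples
#' img <- generateStageImage(5, 512, 100, rngSeed = 1)
#' classLabel(img)
#' @seealso [stripePeriod()] to measure the rendered transversal period.
#' @export
generateStageImage <- function(stage, sidePx = 512L, pixelSizeNm = 100,
                               rngSeed = 1L, sarcomereSpacingUm = NULL,
                               tubuleDiameterUm = NULL) {
  if (!(length(stage) == 1 && stage %in% 1:5)) stop("stage must be in 1..5")
  checkGenArgs(sidePx, pixelSizeNm)
  withSeed(rngSeed, {
    spacing <- if (is.null(sarcomereSpacingUm))
      stats::runif(1, 1.8, 2.0) else sarcomereSpacingUm
    diam <- if (is.null(tubuleDiameterUm))
      stats::runif(1, 0.1, 0.3) else tubuleDiameterUm
    if (spacing < 1.8 || spacing > 2.0)
      stop("sarcomereSpacingUm must lie in [1.8, 2.0]")
    if (diam < 0.1 || diam > 0.3)
      stop("tubuleDiameterUm must lie in [0.1, 0.3]")
    cell <- renderCell(stage, sidePx, pixelSizeNm, spacing, diam)
    SourceImage(applyShotNoise(cell$img), classLabel = stage,
                pixelSizeNm = pixelSizeNm, objectMask = cell$mask,
                sourceId = sprintf("stage%d_seed%d", stage, as.integer(rngSeed)))
  })
}

#' Generate a reject-class (class 0) image
#'
#' Four junk categories occur in mosaic scans of culture wells:
#' \code{empty} frames (background noise only), \code{fragment}s of cells
#' clipped at the frame border, \code{out_of_focus} cells (a stage image
#' convolved with a wide Gaussian kernel), and \code{dead_cell}s showing
#' bright uniform fluorescence without striation.
#'
#' @param kind one of \code{"empty"}, \code{"fragment"},
#'   \code{"out_of_focus"}, \code{"dead_cell"}.
#' @param sidePx image side, 512 or 1024 px.
#' @param pixelSizeNm physical pixel size in nm.
#' @param rngSeed integer seed.
#' @return A \linkS4class{SourceImage} with \code{classLabel = 0}. Fragments
#'   carry a mask clipped at the border; empty images carry an all-FALSE mask.
#' @examples
#' junk <- generateClass0Image("fragment", 512, rngSeed = 3)
#' @export
generateClass0Image <- function(kind, sidePx = 512L, pixelSizeNm = 100,
                                rngSeed = 1L) {
  kinds <- c("empty", "fragment", "out_of_focus", "dead_cell")
  if (!(length(kind) == 1 && kind %in% kinds))
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  checkGenArgs(sidePx, pixelSizeNm)
  withSeed(rngSeed, {
    spacing <- stats::runif(1, 1.8, 2.0)
    diam <- stats::runif(1, 0.1, 0.3)
    out <- switch(kind,
      empty = {
        img <- matrix(BACKGROUND_LEVEL, sidePx, sidePx)
        list(img = img, mask = matrix(FALSE, sidePx, sidePx))
      },
      fragment = {
        # centre pushed towards/over the frame edge so the mask is clipped
        ang <- stats::runif(1, 0, 2 * pi)
        off <- stats::runif(1, 0.45, 0.6)
        renderCell(sample(2:5, 1), sidePx, pixelSizeNm, spacing, diam,
                   centreFrac = off * c(cos(ang), sin(ang)))
      },
      out_of_focus = {
        cell <- renderCell(sample(2:5, 1), sidePx, pixelSizeNm, spacing, diam)
        sigma <- 10 * sidePx / 512
        cell$img <- as.matrix(EBImage::gblur(cell$img, sigma = sigma))
        cell
      },
      dead_cell = renderCell(1, sidePx, pixelSizeNm, spacing, diam,
                             uniformInterior = TRUE))
    SourceImage(applyShotNoise(out$img), classLabel = 0L,
                pixelSizeNm = pixelSizeNm, objectMask = out$mask,
                sourceId = sprintf("class0_%s_seed%d", kind,
                                   as.integer(rngSeed)))
  })
}

#' Generate small non-target distractor objects
#'
#' Distractors emulate non-target structures that naturally occur in
#' confocal mosaic scans (cell fragments, out-of-focus cells). Each raster
#' is cropped tightly to its mask and never exceeds a quarter of the frame
#' side, so its bounding box covers at most 1/16 of the frame area.
#'
#' @param n number of distractors (\code{n = 0} gives an empty list).
#' @param sidePx frame side the distractors are destined for.
#' @param rngSeed integer seed.
#' @return list of \code{list(pixels, mask)} pairs.
#' @examples
#' d <- generateDistractors(3, 512, rngSeed = 7)
#' length(d)
#' @export
generateDistractors <- function(n, sidePx = 512L, rngSeed = 1L) {
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(list())
  withSeed(rngSeed, {
    lapply(seq_len(n), function(i) {
      d <- as.integer(floor(sidePx / 4))
      ix <- seq_len(d) - 1
      dxm <- matrix(rep(ix, d), d) - (d - 1) / 2
      dym <- matrix(rep(ix, each = d), d) - (d - 1) / 2
      th <- stats::runif(1, 0, pi)
      aa <- d * stats::runif(1, 0.2, 0.42)
      bb <- d * stats::runif(1, 0.12, 0.3)
      uu <- cos(th) * dxm + sin(th) * dym
      vv <- -sin(th) * dxm + cos(th) * dym
      rho <- sqrt((uu / aa)^2 + (vv / bb)^2)
      mask <- rho <= 1
      img <- matrix(0, d, d)
      if (stats::runif(1) < 0.5) {        # membrane-ring fragment
        img[mask & rho > 0.82] <- MEMBRANE_LEVEL * stats::runif(1, 0.6, 1)
        img[mask & rho <= 0.82] <- 0.05
      } else {                            # blurred out-of-focus blob
        img[mask] <- stats::runif(1, 0.2, 0.5)
        img <- pmax(as.matrix(EBImage::gblur(img, sigma = max(2, d / 12))), 0)
        mask <- img > 0.02
      }
      keepR <- range(which(rowSums(mask) > 0))
      keepC <- range(which(colSums(mask) > 0))
      list(pixels = img[keepR[1]:keepR[2], keepC[1]:keepC[2], drop = FALSE],
           mask = mask[keepR[1]:keepR[2], keepC[1]:keepC[2], drop = FALSE])
    })
  })
}

#' Write a set of source images to disk with a manifest
#'
#' Images are written as 16-bit grayscale TIFF (intensities clipped to
#' [0, 1]), masks as 8-bit PNG, plus a CSV manifest (source_id, paths,
#' class label, pixel size).
#'
#' @param images list of \linkS4class{SourceImage}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
writeImageSet <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(images, function(img) {
    id <- sourceId(img)
    ipath <- file.path(dir, paste0(id, ".tiff"))
    mpath <- file.path(dir, paste0(id, "_mask.png"))
    EBImage::writeImage(pmin(pixels(img) / max(pixels(img), 1), 1), ipath,
                        type = "tiff", bits.per.sample = 16L)
    EBImage::writeImage(objectMask(img) * 1, mpath, type = "png")
    data.frame(source_id = id, path = ipath, mask_path = mpath,
               class_label = classLabel(img), pixel_size_nm = pixelSize(img),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
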