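#' SourceImage: a labelled single-channel confocal-style raster
#'
#' Container for one source image: a square non-negative intensity matrix,
#' its class label (0 = reject, 1--5 = t-tubule development stage), the
#' physical pixel size in nanometres, and an optional binary object mask
#' marking the target cardiomyocyte. Images of classes 1--5 must carry a
#' non-empty mask; class-0 images without a target object carry an all-FALSE
#' mask.
#'
#' @slot pixels numeric matrix, square, non-negative intensities.
#' @slot classLabel integer in 0..5.
#' @slot pixelSizeNm physical size of one pixel in nm. Full-resolution
#'   acquisitions lie in 58--116 nm/px; sides halve and pixel sizes double
#'   under down-sampling.
#' @slot objectMask logical matrix of the same shape as \code{pixels}.
#' @slot sourceId unique identifier string.
#' @slot variant provenance tag: \code{"original"}, \code{"modified_plain"}
#'   or \code{"modified_distractor"} (the latter two arise from cut-out
#'   compositing augmentation).
#' @exportClass SourceImage
setClass("SourceImage",
  representation(pixels = "matrix", classLabel = "integer",
                 pixelSizeNm = "numeric", objectMask = "matrix",
                 sourceId = "character", variant = "character"),
  prototype(variant = "original"))

setValidity("SourceImage", function(object) {
  px <- object@pixels
  if (nrow(px) != ncol(px)) return("pixels must be square")
  if (any(px < 0)) return("pixel intensities must be non-negative")
  if (!(object@classLabel %in% 0:5)) return("classLabel must be in 0..5")
  if (length(object@pixelSizeNm) != 1 || object@pixelSizeNm <= 0)
    return("pixelSizeNm must be a single positive number")
  if (!identical(dim(object@objectMask), dim(px)))
    return("objectMask shape must match pixels")
  if (!is.logical(object@objectMask)) return("objectMask must be logical")
  if (object@classLabel >= 1L && !any(object@objectMask))
    return("classes 1-5 require a non-empty objectMask")
  if (!(object@variant %in% c("original", "modified_plain",
                              "modified_distractor")))
    return("unknown variant")
  TRUE
})

#' Construct a SourceImage
#'
#' @param pixels square numeric matrix of non-negative intensities.
#' @param classLabel integer class in 0..5.
#' @param pixelSizeNm physical pixel size in nm.
#' @param objectMask logical matrix marking the target cell; defaults to
#'   all-FALSE (only valid for class 0).
#' @param sourceId identifier string.
#' @param variant provenance tag, default \code{"original"}.
#' @return A \linkS4class{SourceImage}.
#' @examples
#' img <- SourceImage(matrix(0.1, 64, 64), classLabel = 0L,
#'                    pixelSizeNm = 116, sourceId = "bg")
#' classLabel(img)
#' @export
SourceImage <- function(pixels, classLabel, pixelSizeNm, objectMask = NULL,
                        sourceId = "img", variant = "original") {
  if (is.null(objectMask))
    objectMask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  new("SourceImage", pixels = pixels, classLabel = as.integer(classLabel),
      pixelSizeNm = pixelSizeNm, objectMask = objectMask,
      sourceId = sourceId, variant = variant)
}

#' DatasetManifest: an augmented sample set over a pool of source images
#'
#' Records every augmented sample as (source, flip, rotation angle, variant)
#' provenance rather than materialised pixels; samples are rendered on
#' demand with \code{\link{materializeSample}}. This keeps manifests of tens
#' of thousands of samples cheap while preserving exact, auditable counts.
#'
#' @slot name set name, e.g. \code{"T-512-A"}.
#' @slot sidePx image side length shared by all samples.
#' @slot samples data.frame with columns sample_id, source_id, class_label,
#'   flip (logical), angle_rad, variant.
#' @slot sources named list of \linkS4class{SourceImage} keyed by source_id.
#' @exportClass DatasetManifest
setClass("DatasetManifest",
  representation(name = "character", sidePx = "integer",
                 samples = "data.frame", sources = "list"))

setValidity("DatasetManifest", function(object) {
  s <- object@samples
  need <- c("sample_id", "source_id", "class_label", "flip", "angle_rad",
            "variant")
  if (!all(need %in% names(s))) return("samples is missing required columns")
  if (anyDuplicated(s$sample_id)) return("sample_id values must be unique")
  key <- paste(s$source_id, s$flip, signif(s$angle_rad, 12), s$variant)
  if (anyDuplicated(key))
    return("(source_id, flip, angle, variant) must be unique")
  if (!all(s$class_label %in% 0:5)) return("class labels must be in 0..5")
  if (!all(s$source_id %in% names(object@sources)))
    return("every sample must reference a known source")
  TRUE
})

#' NetworkSpec: declarative DenseNet stage description
#'
#' An ordered stage list (opening basic dense block, max pooling, alternating
#' bottleneck dense blocks and transition layers, closing dense block, global
#' average pooling, 6-way softmax classifier), with growth parameter k and
#' transition-layer compression factor theta.
#'
#' @slot name preset name.
#' @slot inputSide input image side in px.
#' @slot inputChannels input depth (1 for monochromatic confocal images).
#' @slot k growth parameter: filter count f of every bottleneck dense block
#'   (the stem uses 2k).
#' @slot theta compression factor in (0, 1] applied by transition layers.
#' @slot stages list of stage descriptors (type DBa/MPL/DBb/TL/GAP/C plus
#'   kernel/stride/filter/depth fields).
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(name = "character", inputSide = "integer",
                 inputChannels = "integer", k = "integer", theta = "numeric",
                 stages = "list"))

setValidity("NetworkSpec", function(object) {
  if (object@theta <= 0 || object@theta > 1)
    return("theta must be in (0, 1]")
  if (object@inputSide < 8) return("inputSide too small")
  types <- vapply(object@stages, `[[`, "", "type")
  if (types[1] != "DBa") return("first stage must be the DBa stem")
  if (types[length(types)] != "C") return("last stage must be the classifier")
  if (!"GAP" %in% types) return("spec must contain a global average pooling")
  TRUE
})

#' DenseNetModel: a built (and possibly trained) DenseNet classifier
#'
#' Holds the \linkS4class{NetworkSpec}, all weight arrays, batch
#' normalisation running statistics, and (after training) the optimizer
#' state. Weights live in plain R arrays; the forward/backward engine is
#' implemented in compiled code plus vectorised R.
#'
#' @slot spec the \linkS4class{NetworkSpec} the model was built from.
#' @slot params nested list of weight arrays per stage.
#' @slot state nested list of batch-norm running means/variances.
#' @slot opt ADAM moment estimates (empty until trained).
#' @exportClass DenseNetModel
setClass("DenseNetModel",
  representation(spec = "NetworkSpec", params = "list", state = "list",
                 opt = "list"))
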