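#' Accessors for SourceImage and DatasetManifest
#'
#' \code{pixels}, \code{classLabel}, \code{pixelSize}, \code{objectMask},
#' \code{sourceId} and \code{variantTag} read the corresponding slots of a
#' \linkS4class{SourceImage}; \code{manifestSamples} returns the sample
#' provenance table of a \linkS4class{DatasetManifest} and
#' \code{classCounts} its per-class sample tally.
#'
#' @param x a \linkS4class{SourceImage} or \linkS4class{DatasetManifest}.
#' @return The slot value (matrix, integer, numeric or character), a
#'   data.frame for \code{manifestSamples}, or a named integer vector over
#'   classes 0..5 for \code{classCounts}.
#' @name accessors
#' @examples
#' img <- SourceImage(matrix(0.2, 32, 32), 0L, 116, sourceId = "a")
#' pixelSize(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("objectMask", function(x) standardGeneric("objectMask"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("variantTag", function(x) standardGeneric("variantTag"))
#' @rdname accessors
#' @export
setGeneric("manifestSamples", function(x) standardGeneric("manifestSamples"))
#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname accessors
setMethod("pixels", "SourceImage", function(x) x@pixels)
#' @rdname accessors
setMethod("classLabel", "SourceImage", function(x) x@classLabel)
#' @rdname accessors
setMethod("pixelSize", "SourceImage", function(x) x@pixelSizeNm)
#' @rdname accessors
setMethod("objectMask", "SourceImage", function(x) x@objectMask)
#' @rdname accessors
setMethod("sourceId", "SourceImage", function(x) x@sourceId)
#' @rdname accessors
setMethod("variantTag", "SourceImage", function(x) x@variant)
#' @rdname accessors
setMethod("manifestSamples", "DatasetManifest", function(x) x@samples)
#' @rdname accessors
setMethod("classCounts", "DatasetManifest", function(x) {
  tab <- table(factor(x@samples$class_label, levels = 0:5))
  out <- as.integer(tab)
  names(out) <- paste0("class", 0:5)
  out
})

#' @export
setMethod("show", "SourceImage", function(object) {
  cat(sprintf(
    "SourceImage '%s': %d x %d px, class %d, %.0f nm/px, mask %s, %s\n",
    object@sourceId, nrow(object@pixels), ncol(object@pixels),
    object@classLabel, object@pixelSizeNm,
    if (any(object@objectMask))
      sprintf("%.1f%% of frame", 100 * mean(object@objectMask)) else "empty",
    object@variant))
})

#' @export
setMethod("show", "DatasetManifest", function(object) {
  cc <- classCounts(object)
  cat(sprintf("DatasetManifest '%s': %s samples of %d x %d px from %d sources\n",
              object@name, fmtCount(nrow(object@samples)), object@sidePx,
              object@sidePx, length(object@sources)))
  cat("  per class:", paste(sprintf("%d:%s", 0:5, fmtCount(cc)),
                            collapse = " "), "\n")
})

#' @describeIn manifestLength Number of augmented samples in the manifest.
#' @export
setMethod("length", "DatasetManifest", function(x) nrow(x@samples))

#' Manifest size
#'
#' \code{length()} of a \linkS4class{DatasetManifest} is its sample count.
#' @param x a DatasetManifest.
#' @return integer sample count.
#' @name manifestLength
NULL
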