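# Accessor generics and show methods.

#' Pixel grid of an image-like object
#' @param x a RawImage, BinaryMask, SkeletonImage or SegmentationLabels.
#' @return The underlying matrix: integer intensities for RawImage, logical
#'   for masks and skeletons, integer labels for segmentations.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "RawImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "SkeletonImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "SegmentationLabels", function(x) x@labels)

#' Bit depth of a RawImage
#' @param x a RawImage.
#' @return 8 or 16.
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "RawImage", function(x) x@bitDepth)

#' Physical pixel size
#' @param x a RawImage.
#' @return Pixel size in micrometres per pixel, or `NA`.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "RawImage", function(x) x@pixelSize)

#' Provenance tag
#' @param x a RawImage, SkeletonImage or MorphologyMetrics.
#' @return Character identifier.
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname sourceId
#' @export
setMethod("sourceId", "RawImage", function(x) x@sourceId)

#' @rdname sourceId
#' @export
setMethod("sourceId", "SkeletonImage", function(x) x@sourceMaskId)

#' @rdname sourceId
#' @export
setMethod("sourceId", "MorphologyMetrics", function(x) x@unitId)

#' Number of cells in a segmentation
#' @param x a SegmentationLabels.
#' @return Integer cell count K.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "SegmentationLabels", function(x) x@K)

#' Per-cell pixel areas of a segmentation
#' @param x a SegmentationLabels.
#' @return Integer vector of label areas in px^2.
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' @rdname cellAreas
#' @export
setMethod("cellAreas", "SegmentationLabels", function(x) x@areas)

#' Number of connected components in a skeleton graph
#' @param x a SkeletonGraph.
#' @return Integer component count.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname nComponents
#' @export
setMethod("nComponents", "SkeletonGraph", function(x) length(x@components))

#' Morphology parameter values
#' @param x a MorphologyMetrics.
#' @return Named numeric vector of the 18 parameters (NA = undefined).
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname metricValues
#' @export
setMethod("metricValues", "MorphologyMetrics", function(x) x@values)

#' @export
setMethod("show", "RawImage", function(object) {
  cat(sprintf("RawImage '%s': %d x %d, %d-bit, channel=%s",
              object@sourceId, nrow(object@pixels), ncol(object@pixels),
              object@bitDepth, object@channel))
  if (!is.na(object@pixelSize))
    cat(sprintf(", %.4g um/px", object@pixelSize))
  cat(sprintf("\n  intensity range [%d, %d]\n",
              min(object@pixels), max(object@pixels)))
})

#' @export
setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d, %d foreground px\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels)))
})

#' @export
setMethod("show", "SkeletonImage", function(object) {
  cat(sprintf("SkeletonImage: %d x %d, %d skeleton px\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels)))
})

#' @export
setMethod("show", "SegmentationLabels", function(object) {
  cat(sprintf("SegmentationLabels: %d x %d, K = %d cells\n",
              nrow(object@labels), ncol(object@labels), object@K))
  if (object@K > 0)
    cat("  areas (px^2):", paste(object@areas, collapse = ", "), "\n")
})

#' @export
setMethod("show", "SkeletonGraph", function(object) {
  cls <- vapply(object@components, function(co) co$class, "")
  cat(sprintf(
    "SkeletonGraph: %d components (%d punctate, %d rod, %d network), %d px\n",
    length(cls), sum(cls == "punctate"), sum(cls == "rod"),
    sum(cls == "network"), object@nPixels))
})

#' @export
setMethod("show", "MorphologyMetrics", function(object) {
  cat(sprintf("MorphologyMetrics for unit '%s' (normalizer: %s)\n",
              object@unitId, object@normalizerKind))
  print(round(object@values, 4))
})

#' @export
setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison of '%s' (%s)\n",
              object@metricName, object@test))
  print(object@groupStats, row.names = FALSE)
  cat(sprintf("  statistic = %.4g, p = %.4g, %ssignificant at alpha = %g\n",
              object@statistic, object@pValue,
              if (object@significant) "" else "not ", object@alpha))
  if (nrow(object@tukey)) {
    cat("  Tukey HSD:\n")
    print(object@tukey, row.names = FALSE)
  }
})

#' Coerce a list of MorphologyMetrics to a data.frame
#'
#' @param records a MorphologyMetrics object or list of them.
#' @return data.frame with `unit_id`, the 18 parameters in table order,
#'   `normalizer_kind` and `normalizer_value`.
#' @export
metricsToDataFrame <- function(records) {
  if (is(records, "MorphologyMetrics")) records <- list(records)
  stopifnot(all(vapply(records, is, TRUE, "MorphologyMetrics")))
  if (!length(records)) {
    df <- as.data.frame(setNames(
      rep(list(numeric(0)), length(morphologyParameterNames())),
      morphologyParameterNames()))
    return(cbind(data.frame(unit_id = character(0)), df,
                 data.frame(normalizer_kind = character(0),
                            normalizer_value = numeric(0))))
  }
  vals <- do.call(rbind, lapply(records, function(m) m@values))
  data.frame(
    unit_id = vapply(records, function(m) m@unitId, ""),
    as.data.frame(vals),
    normalizer_kind = vapply(records, function(m) m@normalizerKind, ""),
    normalizer_value = vapply(records, function(m) m@normalizerValue, 0),
    check.names = FALSE, row.names = NULL)
}
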