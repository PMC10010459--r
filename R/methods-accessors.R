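#' @rdname accessors
#' @export
setMethod("rois", "RoiSet", function(object) object@rois)

#' @rdname accessors
#' @export
setMethod("labelImage", "RoiSet", function(object) object@labelImage)

#' @rdname accessors
#' @export
setMethod("pixelSize", "RoiSet", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setMethod("fovArea", "RoiSet", function(object) object@fovArea)

#' @rdname accessors
#' @export
setMethod("pixelSize", "Kymograph", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setMethod("events", "EventTable", function(object) object@events)

#' @rdname accessors
#' @export
setMethod("rasterMatrix", "BinaryRaster", function(object) object@mat)

#' @rdname accessors
#' @export
setMethod("binRate", "BinaryRaster", function(object) object@binRate)

#' @rdname accessors
#' @export
setMethod("pairTable", "PairNetwork", function(object) object@pairs)

#' @rdname accessors
#' @export
setMethod("velocityBins", "VelocityTrace", function(object) object@bins)

#' @rdname accessors
#' @export
setMethod("strengthLevels", "StrengthCurve", function(object) object@levels)

#' @rdname accessors
#' @export
setMethod("curveParameters", "StrengthCurve", function(object) object@derived)

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet: %d ROIs (size filter %d-%d px), %.3g um/px, FOV %.4g mm^2\n",
              nrow(object@rois), object@sizeRange[1], object@sizeRange[2],
              object@pixelSize, object@fovArea))
})

setMethod("show", "EventTable", function(object) {
  e <- object@events
  cat(sprintf("EventTable: %d events across %d ROIs", nrow(e),
              length(unique(e$roi_id))))
  if (!is.na(object@duration)) cat(sprintf(" over %.4g s", object@duration))
  cat("\n")
  if (nrow(e))
    cat(sprintf("  median amplitude %.3g %%dF/F, rise %.3g s, decay %.3g s\n",
                stats::median(e$amplitude), stats::median(e$rise_time, na.rm = TRUE),
                stats::median(e$decay_time, na.rm = TRUE)))
})

setMethod("show", "BinaryRaster", function(object) {
  cat(sprintf("BinaryRaster: %d ROIs x %d bins (%.3g Hz over [%.4g, %.4g] s)\n",
              nrow(object@mat), ncol(object@mat), object@binRate,
              object@window[1], object@window[2]))
})

setMethod("show", "PairNetwork", function(object) {
  p <- object@pairs
  cat(sprintf("PairNetwork: %d pairs, %d included (wcc > %.3g)\n",
              nrow(p), sum(p$included, na.rm = TRUE), object@wccMin))
})

setMethod("show", "VesselResponse", function(object) {
  cat(sprintf("VesselResponse: %d frames at %.3g Hz; baseline %.4g, max dilation %.4g%%\n",
              length(object@series), object@frameRate, object@baselineMin,
              object@maxDilationPct))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d px x %d lines, %.3g um/px at %.5g Hz\n",
              nrow(object@mat), ncol(object@mat), object@pixelSize,
              object@lineRate))
})

setMethod("show", "VelocityTrace", function(object) {
  b <- object@bins
  cat(sprintf("VelocityTrace: %d bins of %.0f ms; median |v| %.3g mm/s (%d low-confidence)\n",
              nrow(b), object@binWidth * 1000,
              stats::median(abs(b$velocity), na.rm = TRUE),
              sum(b$low_confidence, na.rm = TRUE)))
})

setMethod("show", "StrengthCurve", function(object) {
  cat(sprintf("StrengthCurve: %d levels; synaptic fit %s\n",
              nrow(object@levels),
              if (isTRUE(object@converged[2])) "converged" else "flagged"))
  if (length(object@derived))
    print(round(object@derived, 4))
})
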