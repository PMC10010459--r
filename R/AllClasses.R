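#' @import methods
NULL

#' RoiSet: labeled astrocyte regions of interest
#'
#' Container for the output of [detectRois()]: an integer-labeled map of the
#' field of view plus one record per retained region (centroid in micrometers,
#' footprint area in pixels, perivascular flag).
#'
#' @slot labelImage integer matrix; 0 = background, k = pixels of ROI k.
#' @slot rois data.frame with columns `id`, `x_um`, `y_um`, `area_px`,
#'   `is_perivascular`.
#' @slot pixelSize numeric, micrometers per pixel.
#' @slot fovArea numeric, field-of-view area in mm^2.
#' @slot sizeRange numeric length 2, the pixel-area filter the set was built
#'   with (default 600-6000 px).
#' @exportClass RoiSet
setClass("RoiSet",
  representation(labelImage = "matrix", rois = "data.frame",
                 pixelSize = "numeric", fovArea = "numeric",
                 sizeRange = "numeric"),
  prototype(pixelSize = 1, fovArea = NA_real_, sizeRange = c(600, 6000)))

setValidity("RoiSet", function(object) {
  msg <- NULL
  r <- object@rois
  need <- c("id", "x_um", "y_um", "area_px")
  if (!all(need %in% names(r)))
    msg <- c(msg, paste("rois must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(r$id)) msg <- c(msg, "ROI ids must be unique")
    if (nrow(r) && (any(r$area_px < object@sizeRange[1]) ||
                    any(r$area_px > object@sizeRange[2])))
      msg <- c(msg, "every retained ROI must satisfy the configured size filter")
  }
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  if (!is.na(object@fovArea) && object@fovArea <= 0)
    msg <- c(msg, "fovArea must be positive")
  if (is.null(msg)) TRUE else msg
})

#' EventTable: detected calcium transients
#'
#' One row per detected transient: onset/peak times, supra-threshold span,
#' amplitude (%dF/F), 10-90% rise time, half-decay time, and the analysis
#' window the event falls in (baseline / stimulation / recovery).
#'
#' @slot events data.frame with columns `roi_id`, `onset_time`, `peak_time`,
#'   `span_end`, `amplitude`, `rise_time`, `decay_time`, `decay_censored`,
#'   `window_label`.
#' @slot duration numeric, seconds of recording the table was extracted from.
#' @slot samplingRate numeric, Hz.
#' @exportClass EventTable
setClass("EventTable",
  representation(events = "data.frame", duration = "numeric",
                 samplingRate = "numeric"),
  prototype(duration = NA_real_, samplingRate = NA_real_))

setValidity("EventTable", function(object) {
  e <- object@events
  need <- c("roi_id", "onset_time", "peak_time", "amplitude")
  if (!all(need %in% names(e)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$amplitude <= 0)) return("event amplitudes must be positive")
    if (any(e$onset_time > e$peak_time + 1e-9))
      return("event onset must not follow its peak")
  }
  TRUE
})

#' BinaryRaster: binarized event occupancy per ROI per time bin
#'
#' @slot mat integer matrix (ROIs x bins) with entries in {0, 1}.
#' @slot binRate numeric, bins per second (default 2 Hz).
#' @slot window numeric length 2, analysis window in seconds.
#' @exportClass BinaryRaster
setClass("BinaryRaster",
  representation(mat = "matrix", binRate = "numeric", window = "numeric"))

setValidity("BinaryRaster", function(object) {
  if (!all(object@mat %in% c(0L, 1L))) return("raster entries must be 0/1")
  expected <- round(object@binRate * diff(object@window))
  if (ncol(object@mat) != expected)
    return(sprintf("raster must have binRate x window length = %d bins", expected))
  TRUE
})

#' PairNetwork: per-pair correlation records and inclusion flags
#'
#' @slot pairs data.frame with columns `roi_i`, `roi_j`, `cc`, `wcc`,
#'   `distance_um`, `included`.
#' @slot wccMin numeric, inclusion threshold on the weighted cc (default 0.02).
#' @slot ccLinkMin numeric, correlogram display cutoff on cc (default 0.4).
#' @slot nSamplesPerRoi integer, bins per ROI the raster supplied.
#' @exportClass PairNetwork
setClass("PairNetwork",
  representation(pairs = "data.frame", wccMin = "numeric",
                 ccLinkMin = "numeric", nSamplesPerRoi = "integer"),
  prototype(wccMin = 0.02, ccLinkMin = 0.4))

setValidity("PairNetwork", function(object) {
  p <- object@pairs
  need <- c("roi_i", "roi_j", "cc", "wcc", "included")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  ok <- is.finite(p$cc)
  if (any(abs(p$cc[ok]) > 1 + 1e-12)) return("cc must lie in [-1, 1]")
  if (any(abs(p$wcc[ok]) > abs(p$cc[ok]) + 1e-12))
    return("|wcc| must not exceed |cc|")
  TRUE
})

#' VesselResponse: arteriole lumen time series with dilation metrics
#'
#' @slot series numeric, lumen measure (cross-sectional area proxy) per frame.
#' @slot frameRate numeric, Hz (default 2).
#' @slot stimWindow numeric length 2, stimulation window in seconds.
#' @slot baselineMin numeric, lower-5th-percentile baseline.
#' @slot maxDilationPct numeric, 100 x max / baseline.
#' @slot latencyToMax numeric, seconds from stimulus onset to the maximum.
#' @slot ascendingSlope,descendingSlope numeric, %-of-baseline per second.
#' @slot censored logical, TRUE when kinetics could not be measured.
#' @exportClass VesselResponse
setClass("VesselResponse",
  representation(series = "numeric", frameRate = "numeric",
                 stimWindow = "numeric", baselineMin = "numeric",
                 maxDilationPct = "numeric", latencyToMax = "numeric",
                 ascendingSlope = "numeric", descendingSlope = "numeric",
                 censored = "logical"),
  prototype(frameRate = 2, baselineMin = NA_real_, maxDilationPct = NA_real_,
            latencyToMax = NA_real_, ascendingSlope = NA_real_,
            descendingSlope = NA_real_, censored = FALSE))

setValidity("VesselResponse", function(object) {
  if (object@frameRate <= 0) return("frameRate must be positive")
  if (!is.na(object@baselineMin) && length(object@series) &&
      object@baselineMin > min(object@series) + 1e-6 * abs(min(object@series)) + 1e-12)
    return("baselineMin cannot exceed the series minimum")
  TRUE
})

#' Kymograph: line-scan matrix with acquisition metadata
#'
#' Space-by-time matrix from repeated one-dimensional scans across a
#' capillary; moving red blood cells appear as slanted streaks.
#'
#' @slot mat numeric matrix, rows = spatial pixels, columns = scan lines.
#' @slot pixelSize numeric, micrometers per spatial pixel.
#' @slot lineRate numeric, lines per second (Hz).
#' @exportClass Kymograph
setClass("Kymograph",
  representation(mat = "matrix", pixelSize = "numeric", lineRate = "numeric"))

setValidity("Kymograph", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (object@lineRate <= 0) return("lineRate must be positive")
  TRUE
})

#' VelocityTrace: binned radon velocity estimates
#'
#' @slot bins data.frame with columns `bin_center`, `velocity`, `confidence`,
#'   `low_confidence`, `saturated`, `smoothed`.
#' @slot binWidth numeric, seconds per bin (default 0.050).
#' @slot smoothWindow numeric, moving-average window in seconds (default 0.750).
#' @exportClass VelocityTrace
setClass("VelocityTrace",
  representation(bins = "data.frame", binWidth = "numeric",
                 smoothWindow = "numeric"),
  prototype(binWidth = 0.05, smoothWindow = NA_real_))

#' StrengthCurve: synaptic input-output curve with sigmoid fits
#'
#' Per-stimulus-level fiber-volley amplitude, EPSP slope and their ratio,
#' with three-parameter Boltzmann sigmoid fits of FV vs stimulus and EPSP
#' slope vs FV, and the derived parameter set (maximal FV, half-maximal FV,
#' curve slope, maximal EPSP slope, maximal ratio, EPSP slope at population
#' spike threshold).
#'
#' @slot levels data.frame with columns `level`, `fv_amplitude`, `epsp_slope`,
#'   `ratio`, `ps_present`.
#' @slot fvFit,synFit named numeric vectors `(max_response, half_max_input,
#'   slope_factor)` or NA on non-convergence.
#' @slot derived named numeric vector of the extracted curve parameters.
#' @slot converged logical length 2 (FV fit, synaptic fit).
#' @exportClass StrengthCurve
setClass("StrengthCurve",
  representation(levels = "data.frame", fvFit = "numeric", synFit = "numeric",
                 derived = "numeric", converged = "logical"))

setValidity("StrengthCurve", function(object) {
  lv <- object@levels
  need <- c("level", "fv_amplitude", "epsp_slope", "ratio")
  if (!all(need %in% names(lv)))
    return(paste("levels must have columns:", paste(need, collapse = ", ")))
  ok <- lv$fv_amplitude > 0 & is.finite(lv$ratio)
  if (any(abs(lv$ratio[ok] - lv$epsp_slope[ok] / lv$fv_amplitude[ok]) > 1e-9))
    return("ratio must equal epsp_slope / fv_amplitude")
  TRUE
})
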