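#' Binarize detected events onto a fixed-rate raster
#'
#' A bin is 1 exactly when any part of an event's supra-threshold span
#' overlaps the half-open bin `[t, t + 1/binRate)`. The default 2 Hz rate
#' over a 60 s window gives 120 samples per ROI (and a per-pair denominator
#' of 240).
#'
#' @param eventTable an [EventTable] whose events carry `span_start` /
#'   `span_end` columns (as produced by [detectEvents()]).
#' @param roiIds integer ids defining the raster rows (silent ROIs give
#'   all-zero rows).
#' @param binRate bins per second (default 2).
#' @param window numeric length 2, seconds (default `c(0, 60)`); must lie
#'   within the recording.
#' @return a [BinaryRaster].
#' @export
binarizeEvents <- function(eventTable, roiIds, binRate = 2, window = c(0, 60)) {
  dur <- eventTable@duration
  if (!is.na(dur) && (window[1] < 0 || window[2] > dur + 1e-9))
    stop("analysis window lies outside the recording")
  nBins <- round(binRate * diff(window))
  edges <- window[1] + seq(0, nBins) / binRate
  ev <- events(eventTable)
  s0 <- if ("span_start" %in% names(ev)) ev$span_start else ev$onset_time
  s1 <- if ("span_end" %in% names(ev)) ev$span_end else ev$peak_time
  m <- matrix(0L, nrow = length(roiIds), ncol = nBins,
              dimnames = list(as.character(roiIds), NULL))
  for (k in seq_len(nrow(ev))) {
    r <- match(ev$roi_id[k], roiIds)
    if (is.na(r)) next
    hit <- which(s1[k] > edges[-length(edges)] & s0[k] < edges[-1])
    m[r, hit] <- 1L
  }
  new("BinaryRaster", mat = m, binRate = binRate, window = window)
}

#' Pearson correlation of two binarized event rows
#'
#' The plain product-moment correlation of two 0/1 vectors (the phi
#' coefficient). Constant rows have no defined correlation; the pair is
#' excluded rather than erroring.
#'
#' @param raster a [BinaryRaster].
#' @param i,j row indices.
#' @return the correlation, or `NA` with a warning for constant rows.
#' @export
pairCC <- function(raster, i, j) {
  x <- rasterMatrix(raster)[i, ]
  y <- rasterMatrix(raster)[j, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning(sprintf("pair (%d, %d): constant row, cc undefined", i, j))
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Weighted correlation coefficient of an ROI pair
#'
#' The pair correlation scaled by the pair's event occupancy: the cc is
#' multiplied by the number of event samples across the two rows divided by
#' the total sample count of the pair (2 x samples per ROI; 240 for the
#' default 2 Hz x 60 s raster). This down-weights pairs whose correlation
#' rests on very few coactive samples.
#'
#' @param cc correlation from [pairCC()].
#' @param raster a [BinaryRaster].
#' @param i,j row indices.
#' @param coincident if TRUE use the count of coincident (both-1) bins x 2
#'   instead of the total 1-bins across both rows.
#' @return the weighted cc (same sign as cc, never larger in magnitude).
#' @export
weightedCC <- function(cc, raster, i, j, coincident = FALSE) {
  if (is.na(cc)) return(NA_real_)
  m <- rasterMatrix(raster)
  denom <- 2 * ncol(m)
  nev <- if (coincident) 2 * sum(m[i, ] == 1 & m[j, ] == 1)
         else sum(m[i, ]) + sum(m[j, ])
  cc * nev / denom
}

#' Build the per-pair network table
#'
#' Computes cc and weighted cc for every ROI pair of a raster, attaches
#' centroid distances, and flags inclusion by the weighted-cc threshold
#' (pairs with wcc > `wccMin` are included; the default 0.02 is the analysis
#' inclusion cutoff).
#'
#' @param raster a [BinaryRaster] whose rownames are ROI ids.
#' @param distances data.frame from [pairwiseDistances()] (optional).
#' @param wccMin inclusion threshold on wcc (default 0.02, strict >).
#' @param ccLinkMin correlogram display cutoff on cc (default 0.4).
#' @param coincident passed to [weightedCC()].
#' @return a [PairNetwork].
#' @export
buildPairNetwork <- function(raster, distances = NULL, wccMin = 0.02,
                             ccLinkMin = 0.4, coincident = FALSE) {
  m <- rasterMatrix(raster)
  ids <- as.integer(rownames(m))
  if (!length(ids) || anyNA(ids)) ids <- seq_len(nrow(m))
  n <- nrow(m)
  if (n < 2) stop("need at least 2 ROIs")
  cmb <- utils::combn(n, 2)
  cc <- wcc <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    cc[k] <- suppressWarnings(pairCC(raster, cmb[1, k], cmb[2, k]))
    wcc[k] <- weightedCC(cc[k], raster, cmb[1, k], cmb[2, k], coincident)
  }
  p <- data.frame(roi_i = ids[cmb[1, ]], roi_j = ids[cmb[2, ]],
                  cc = cc, wcc = wcc, distance_um = NA_real_)
  if (!is.null(distances)) {
    key <- paste(pmin(p$roi_i, p$roi_j), pmax(p$roi_i, p$roi_j))
    dkey <- paste(pmin(distances$roi_i, distances$roi_j),
                  pmax(distances$roi_i, distances$roi_j))
    p$distance_um <- distances$distance_um[match(key, dkey)]
  }
  p$included <- !is.na(p$wcc) & p$wcc > wccMin
  new("PairNetwork", pairs = p, wccMin = wccMin, ccLinkMin = ccLinkMin,
      nSamplesPerRoi = ncol(m))
}

#' FOV-level network summary
#'
#' Coactive-connection density (included pairs per mm^2), the mean distance
#' between coactive ROIs (over pairs whose cc lies in the correlogram display
#' range, default 0.4-1), the density of correlated ROIs (ROIs participating
#' in at least one included pair, per mm^2), and the FOV gate: a FOV is kept
#' only when its correlated-ROI density strictly exceeds `fovDensityMin`
#' (default 100 per mm^2).
#'
#' @param network a [PairNetwork] (or a named list of them, one per analysis
#'   window, summarized per window).
#' @param fovAreaMm2 field-of-view area in mm^2.
#' @param fovDensityMin correlated-ROI density gate, per mm^2 (default 100,
#'   strict >).
#' @param countPairs if TRUE the gate counts included pairs instead of
#'   participating ROIs.
#' @return data.frame with one row per window: `window`,
#'   `coactive_pairs_per_mm2`, `mean_pair_distance_um`,
#'   `correlated_rois_per_mm2`, `fov_included`.
#' @export
networkSummary <- function(network, fovAreaMm2, fovDensityMin = 100,
                           countPairs = FALSE) {
  if (fovAreaMm2 <= 0) stop("FOV area must be known and positive")
  nets <- if (is(network, "PairNetwork")) list(all = network) else network
  out <- lapply(names(nets), function(w) {
    p <- pairTable(nets[[w]])
    inc <- p[p$included, , drop = FALSE]
    link <- p[!is.na(p$cc) & p$cc >= nets[[w]]@ccLinkMin & p$cc <= 1, ,
              drop = FALSE]
    nCorr <- length(unique(c(inc$roi_i, inc$roi_j)))
    dens <- (if (countPairs) nrow(inc) else nCorr) / fovAreaMm2
    data.frame(window = w,
               coactive_pairs_per_mm2 = nrow(inc) / fovAreaMm2,
               mean_pair_distance_um =
                 if (nrow(link)) mean(link$distance_um) else NA_real_,
               correlated_rois_per_mm2 = nCorr / fovAreaMm2,
               fov_included = dens > fovDensityMin,
               zero_pairs = nrow(inc) == 0)
  })
  do.call(rbind, out)
}

#' Density of active ROIs per mm^2
#'
#' @param eventTable an [EventTable].
#' @param fovAreaMm2 FOV area in mm^2.
#' @param window optional `(start, end)` seconds; events whose peak falls in
#'   the window count the ROI as active.
#' @return active ROIs per mm^2.
#' @export
activeRoiDensity <- function(eventTable, fovAreaMm2, window = NULL) {
  if (fovAreaMm2 <= 0) stop("FOV area must be known and positive")
  ev <- events(eventTable)
  if (!is.null(window))
    ev <- ev[ev$peak_time >= window[1] & ev$peak_time < window[2], ,
             drop = FALSE]
  length(unique(ev$roi_id)) / fovAreaMm2
}

#' Mean per-ROI event rate within a window
#'
#' Event count per ROI within the window divided by the window length (Hz),
#' averaged across the ROIs active in the window; used for the oscillation
#' frequency during stimulation.
#'
#' @param eventTable an [EventTable].
#' @param window `(start, end)` seconds.
#' @return mean events per second per active ROI (0 when no events).
#' @export
oscillationFrequency <- function(eventTable, window) {
  len <- diff(window)
  if (len <= 0) stop("window length must be positive")
  ev <- events(eventTable)
  ev <- ev[ev$peak_time >= window[1] & ev$peak_time < window[2], , drop = FALSE]
  if (!nrow(ev)) return(0)
  mean(table(ev$roi_id) / len)
}

#' Node/edge tables for the correlogram
#'
#' Node weight is the sum of weighted ccs over a ROI's included partners
#' (dot size in the correlogram); edges carry the unweighted cc and are
#' restricted to the display range `[ccLinkMin, 1]`.
#'
#' @param network a [PairNetwork].
#' @param roiset a [RoiSet] supplying node positions (optional).
#' @return list of data.frames `nodes` (`id`, `weight`, and `x_um`/`y_um`
#'   when positions are available) and `edges` (`roi_i`, `roi_j`, `cc`).
#' @export
exportCorrelogram <- function(network, roiset = NULL) {
  p <- pairTable(network)
  ids <- sort(unique(c(p$roi_i, p$roi_j)))
  inc <- p[p$included, , drop = FALSE]
  w <- vapply(ids, function(id)
    sum(inc$wcc[inc$roi_i == id | inc$roi_j == id]), 0)
  nodes <- data.frame(id = ids, weight = w)
  if (!is.null(roiset)) {
    r <- rois(roiset)
    nodes$x_um <- r$x_um[match(ids, r$id)]
    nodes$y_um <- r$y_um[match(ids, r$id)]
  }
  edges <- p[!is.na(p$cc) & p$cc >= network@ccLinkMin & p$cc <= 1,
             c("roi_i", "roi_j", "cc")]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
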