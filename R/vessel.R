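#' Per-frame lumen area from a rhodamine channel frame
#'
#' Otsu threshold computed within the supplied vessel ROI; the lumen measure
#' is the above-threshold pixel count times the pixel area. Because the
#' threshold is relative to the frame's own histogram, the measure is
#' invariant to uniform intensity scaling.
#'
#' @param frame numeric matrix (rhodamine channel).
#' @param vesselRoi logical matrix of the same shape marking the vessel
#'   region the threshold is computed in.
#' @param pixelSize um per pixel.
#' @return lumen area in um^2, or `NA` with attribute `missing_frame = TRUE`
#'   when no pixel clears the threshold.
#' @export
segmentLumen <- function(frame, vesselRoi, pixelSize = 1) {
  if (!identical(dim(frame), dim(vesselRoi)))
    stop("frame and vesselRoi must have the same shape")
  v <- as.numeric(frame[vesselRoi])
  rng <- range(v)
  if (diff(rng) == 0) {
    out <- NA_real_; attr(out, "missing_frame") <- TRUE
    return(out)
  }
  vn <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(vn, nrow = 1)), range = c(0, 1))
  n <- sum(vn > thr)
  if (n == 0) {
    out <- NA_real_; attr(out, "missing_frame") <- TRUE
    return(out)
  }
  n * pixelSize^2
}

#' Lower-fifth-percentile baseline of a lumen series
#'
#' The baseline ("minimum volume") is the mean of the smallest
#' `ceiling(0.05 n)` measurements, which guards the minimum against
#' single-frame motion artifacts.
#'
#' @param series numeric lumen measurements (length >= 20 so the lower 5%
#'   holds at least one full point).
#' @return the baseline value.
#' @export
baselineMinimum <- function(series) {
  series <- series[is.finite(series)]
  if (length(series) < 20)
    stop("need >= 20 measurements so the lower fifth percentile is populated; record a longer series")
  k <- ceiling(0.05 * length(series))
  mean(sort(series)[seq_len(k)])
}

#' Maximal dilation as percent of baseline
#'
#' `100 * max(series) / baselineMin`; 100% means no dilation.
#'
#' @param series numeric lumen series.
#' @param baselineMin baseline from [baselineMinimum()].
#' @return max dilation in percent of baseline.
#' @export
maxDilation <- function(series, baselineMin) {
  if (!is.finite(baselineMin) || baselineMin <= 0)
    stop("baseline must be positive")
  100 * max(series, na.rm = TRUE) / baselineMin
}

#' Dilation kinetics: latency to maximum and rise/fall slopes
#'
#' Latency is the time from stimulus onset to the series maximum within the
#' stimulation-plus-post window. The ascending and descending slopes are
#' linear fits over the 20-80% amplitude segments on each side of the peak,
#' expressed in percent of baseline per second. Frames more than
#' `artifactSd` SDs below baseline are excluded as motion artifacts.
#'
#' @param series numeric lumen series.
#' @param time numeric, seconds.
#' @param stimWindow `(onset, end)` of stimulation in seconds; the search
#'   extends `postS` seconds past the end.
#' @param baselineMin baseline from [baselineMinimum()].
#' @param postS seconds after stimulation included in the search (default 30).
#' @param artifactSd artifact exclusion threshold in baseline SDs (default 5).
#' @return list with `latency_to_max`, `ascending_slope`, `descending_slope`
#'   (%-of-baseline / s) and `censored` (TRUE when the peak sits at the
#'   window edge or the series is flat).
#' @export
dilationKinetics <- function(series, time, stimWindow, baselineMin,
                             postS = 30, artifactSd = 5) {
  pre <- series[time < stimWindow[1]]
  sdB <- stats::sd(pre)
  if (is.finite(sdB) && sdB > 0)
    series[series < baselineMin - artifactSd * sdB] <- NA
  inW <- which(time >= stimWindow[1] & time <= stimWindow[2] + postS &
                 is.finite(series))
  out <- list(latency_to_max = NA_real_, ascending_slope = NA_real_,
              descending_slope = NA_real_, censored = TRUE)
  if (length(inW) < 3) return(out)
  pk <- inW[which.max(series[inW])]
  amp <- series[pk] - baselineMin
  if (amp <= 0 || pk == inW[1] || pk == inW[length(inW)]) return(out)
  out$latency_to_max <- time[pk] - stimWindow[1]
  out$censored <- FALSE
  pct <- 100 * (series - baselineMin) / baselineMin
  ampPct <- pct[pk]
  segFit <- function(idx) {
    sel <- idx[is.finite(pct[idx]) & pct[idx] >= 0.2 * ampPct &
                 pct[idx] <= 0.8 * ampPct]
    if (length(sel) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(pct[sel] ~ time[sel]))[2])
  }
  out$ascending_slope <- segFit(inW[1]:pk)
  out$descending_slope <- segFit(pk:inW[length(inW)])
  out
}

#' Interval between vessel dilation peak and end-foot calcium peak
#'
#' Signed difference T2 - T1 between the end-foot %dF/F peak time (T2) and
#' the vessel dilation peak time (T1) on a shared time base; positive when
#' the calcium peak follows the dilation peak.
#'
#' @param vesselSeries numeric lumen series.
#' @param endfootDff numeric end-foot %dF/F series, same time base.
#' @param time numeric, seconds.
#' @return the interval in seconds, or `NA` with attribute `censored = TRUE`
#'   when either series has no interior peak.
#' @export
endfootTiming <- function(vesselSeries, endfootDff, time) {
  pkOf <- function(x) {
    i <- which.max(x)
    if (i == 1 || i == length(x) || !is.finite(x[i])) NA_integer_ else i
  }
  i1 <- pkOf(vesselSeries); i2 <- pkOf(endfootDff)
  if (is.na(i1) || is.na(i2)) {
    out <- NA_real_; attr(out, "censored") <- TRUE
    return(out)
  }
  time[i2] - time[i1]
}

#' Vessel leakiness ratio series
#'
#' Per timepoint, the FOV-mean rhodamine over FOV-mean EGFP ratio, itself
#' normalized to the 0 min timepoint:
#' `r_t = (rhod_t / egfp_t) / (rhod_0 / egfp_0)`, so `r_0 = 1` exactly and
#' any gain applied equally to both channels cancels.
#'
#' @param rhodamine,egfp numeric vectors of FOV mean intensities, one per
#'   timepoint.
#' @param timepointsMin numeric, minutes (default `c(0, 15, 30, 45, 60)`).
#' @return data.frame `timepoint_min`, `rhodamine_mean`, `egfp_mean`,
#'   `ratio_to_t0`.
#' @export
leakinessRatio <- function(rhodamine, egfp,
                           timepointsMin = c(0, 15, 30, 45, 60)) {
  if (length(rhodamine) != length(egfp) ||
      length(rhodamine) != length(timepointsMin))
    stop("both channels must be present at every timepoint")
  if (any(!is.finite(egfp)) || any(egfp == 0))
    stop("zero or missing EGFP mean")
  ch <- rhodamine / egfp
  data.frame(timepoint_min = timepointsMin, rhodamine_mean = rhodamine,
             egfp_mean = egfp, ratio_to_t0 = ch / ch[1])
}

#' Vessel width histogram with fixed half-open bins
#'
#' Widths are counted into half-open bins `[k w, (k+1) w)` of width `w`
#' (default 0.5 um), the binning used for microvessel size distributions.
#'
#' @param widths positive vessel widths in um.
#' @param binWidth bin width in um (default 0.5).
#' @return data.frame `bin_lo`, `bin_hi`, `count`, `frequency`.
#' @export
widthHistogram <- function(widths, binWidth = 0.5) {
  if (!length(widths)) stop("empty width list")
  if (any(widths <= 0)) stop("widths must be positive")
  k <- floor(widths / binWidth)
  top <- max(k)
  count <- tabulate(k + 1, nbins = top + 1)
  data.frame(bin_lo = (0:top) * binWidth, bin_hi = (1:(top + 1)) * binWidth,
             count = count, frequency = count / length(widths))
}

#' Two-sample Kolmogorov-Smirnov comparison of width distributions
#'
#' @param widthsA,widthsB the two raw width samples (um).
#' @return list with `D` (max ECDF difference) and `p` (asymptotic).
#' @export
compareWidths <- function(widthsA, widthsB) {
  kt <- suppressWarnings(stats::ks.test(widthsA, widthsB, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
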