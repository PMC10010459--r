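#' Normalize a raw fluorescence trace to percent dF/F
#'
#' `100 * (F - F0) / F0` with `F0` the mean over the pre-stimulus baseline
#' window, so the baseline of the normalized trace sits at zero and the
#' result is invariant to multiplicative rescaling of the raw trace.
#'
#' @param trace numeric raw fluorescence series.
#' @param time numeric, seconds, same length as `trace`.
#' @param baselineWindow numeric length 2, `(start, end)` seconds.
#' @return numeric %dF/F series with attributes `F0` and `baselineWindow`.
#' @export
computeDff <- function(trace, time, baselineWindow) {
  inB <- time >= baselineWindow[1] & time < baselineWindow[2]
  if (sum(inB) < 2) stop("baseline window must contain at least 2 samples")
  f0 <- mean(trace[inB])
  if (!is.finite(f0) || f0 <= 0)
    stop("non-positive baseline fluorescence: dead ROI")
  dff <- 100 * (trace - f0) / f0
  attr(dff, "F0") <- f0
  attr(dff, "baselineWindow") <- baselineWindow
  dff
}

# centered boxcar smoothing with edge truncation
.boxcar <- function(x, k) {
  if (k <= 1) return(x)
  half <- floor(k / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# locate threshold-crossing runs and their local peaks in one %dF/F trace;
# promMin is the minimum prominence (peak minus the valley separating it
# from a taller peak) a secondary peak needs to count as its own event
.detectOne <- function(dff, time, thr, minSep, minDur = 1, valleyFrac = 0.5,
                       promMin = 0) {
  above <- dff > thr
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  dt <- time[2] - time[1]
  # sub-threshold gaps briefer than minSep do not terminate an event
  i0s <- starts[runs]; i1s <- ends[runs]
  if (length(runs) > 1) {
    merged0 <- i0s[1]; merged1 <- i1s[1]
    for (k in 2:length(runs)) {
      if ((i0s[k] - merged1[length(merged1)]) * dt < minSep)
        merged1[length(merged1)] <- i1s[k]
      else { merged0 <- c(merged0, i0s[k]); merged1 <- c(merged1, i1s[k]) }
    }
    i0s <- merged0; i1s <- merged1
  }
  out <- list()
  for (k in seq_along(i0s)) {
    i0 <- i0s[k]; i1 <- i1s[k]
    if ((i1 - i0 + 1) * dt < minDur) next   # too brief to be a transient
    seg <- dff[i0:i1]
    # local maxima within the run
    pk <- which(diff(sign(diff(c(-Inf, seg, -Inf)))) < 0)
    pkAbs <- i0 + pk - 1
    pkAbs <- pkAbs[dff[pkAbs] > thr]
    # keep a peak only if it is far from every taller kept peak, stands out
    # by at least promMin above the valley between them, and that valley
    # descends at least `valleyFrac` of the way back to threshold;
    # otherwise it is a shoulder of the same event
    if (length(pkAbs) > 1) {
      ordv <- order(dff[pkAbs], decreasing = TRUE)
      kept <- integer(0)
      for (p in pkAbs[ordv]) {
        ok <- TRUE
        for (q in kept) {
          sep <- abs(time[p] - time[q]) >= minSep
          valley <- min(dff[min(p, q):max(p, q)])
          deep <- valley < thr + (1 - valleyFrac) * (min(dff[p], dff[q]) - thr)
          prom <- dff[p] - valley >= promMin
          if (!sep || !deep || !prom) { ok <- FALSE; break }
        }
        if (ok) kept <- c(kept, p)
      }
      pkAbs <- sort(kept)
    }
    for (m in seq_along(pkAbs)) {
      onset <- if (m == 1) time[i0] else {
        # secondary peaks start at the minimum between peaks
        lo <- pkAbs[m - 1]:pkAbs[m]
        time[lo[which.min(dff[lo])]]
      }
      out[[length(out) + 1L]] <- data.frame(
        onset_time = onset, peak_time = time[pkAbs[m]],
        peak_index = pkAbs[m], span_start = time[i0],
        span_end = time[i1] + dt, peak_value = dff[pkAbs[m]])
    }
  }
  do.call(rbind, out)
}

#' Detect supra-threshold calcium events in %dF/F traces
#'
#' The per-ROI threshold is derived from the pre-stimulus baseline period:
#' baseline mean + `kSd` baseline SDs on the %dF/F trace. Each contiguous
#' supra-threshold excursion yields one event per local peak, with peaks
#' closer than `minSeparation` merged into the taller one. Events are labeled
#' by the analysis window their peak falls in.
#'
#' @param dffMat numeric matrix (samples x ROIs) of %dF/F traces, or a single
#'   numeric vector.
#' @param time numeric, seconds.
#' @param baselineWindow numeric length 2, the pre-stimulus period the
#'   threshold is derived from.
#' @param kSd threshold multiplier on the baseline SD (default 2).
#' @param minSeparation minimum peak separation in seconds (default 1).
#' @param minDuration minimum supra-threshold duration of an event in
#'   seconds (default 1); briefer excursions are treated as noise.
#' @param minAmpSd minimum event amplitude (and minimum prominence of a
#'   secondary peak), in multiples of the raw baseline SD (default 4).
#'   The run threshold stays at `kSd`; this gate rejects slow noise bumps
#'   riding the decay tail of a large transient.
#' @param smoothS boxcar width in seconds applied before thresholding and
#'   peak finding (default 0.5); the threshold is derived from the baseline
#'   of the same smoothed trace.
#' @param valleyFrac fraction of the way back to threshold the trace must
#'   descend between two peaks of one excursion for them to count as
#'   separate events (default 0.5).
#' @param windows optional named list of `(start, end)` windows (e.g.
#'   `list(baseline = c(0, 600), stimulation = c(600, 610))`) used to label
#'   events; unlabeled events get `NA`.
#' @return an [EventTable]; kinetics columns are filled by [eventKinetics()].
#' @export
detectEvents <- function(dffMat, time, baselineWindow, kSd = 2,
                         minSeparation = 1, minDuration = 1, minAmpSd = 4,
                         smoothS = 0.5, valleyFrac = 0.5, windows = NULL) {
  if (is.null(dim(dffMat))) dffMat <- matrix(dffMat, ncol = 1)
  if (all(is.na(dffMat))) stop("all-NA trace")
  inB <- time >= baselineWindow[1] & time < baselineWindow[2]
  dt <- time[2] - time[1]
  kbox <- max(1, round(smoothS / dt))
  evs <- list()
  for (r in seq_len(ncol(dffMat))) {
    x <- .boxcar(dffMat[, r], kbox)
    sdB <- stats::sd(x[inB])
    sdRaw <- stats::sd(dffMat[inB, r])
    thr <- mean(x[inB]) + kSd * sdB
    d <- .detectOne(x, time, thr, minSeparation, minDuration, valleyFrac,
                    promMin = minAmpSd * sdRaw)
    if (is.null(d)) next
    d$roi_id <- r
    d$threshold <- thr
    kin <- lapply(seq_len(nrow(d)), function(i)
      eventKinetics(x, time, d[i, ]))
    d$amplitude <- vapply(kin, `[[`, 0, "amplitude")
    d$rise_time <- vapply(kin, `[[`, 0, "rise_time")
    d$decay_time <- vapply(kin, `[[`, 0, "decay_time")
    d$decay_censored <- vapply(kin, `[[`, TRUE, "decay_censored")
    # noise riding on the slow tail of a transient can re-cross the global
    # threshold; require the local-baseline amplitude to clear the
    # minAmpSd x raw-SD criterion as well
    d <- d[d$amplitude > minAmpSd * sdRaw, , drop = FALSE]
    evs[[length(evs) + 1L]] <- d
  }
  ev <- if (length(evs)) do.call(rbind, evs) else
    data.frame(onset_time = numeric(), peak_time = numeric(),
               peak_index = integer(), span_start = numeric(),
               span_end = numeric(), peak_value = numeric(),
               roi_id = integer(), threshold = numeric(),
               amplitude = numeric(), rise_time = numeric(),
               decay_time = numeric(), decay_censored = logical())
  ev <- ev[ev$amplitude > 0, , drop = FALSE]
  ev$window_label <- rep(NA_character_, nrow(ev))
  if (!is.null(windows) && nrow(ev))
    for (w in names(windows)) {
      inW <- ev$peak_time >= windows[[w]][1] & ev$peak_time < windows[[w]][2]
      ev$window_label[inW] <- w
    }
  rownames(ev) <- NULL
  new("EventTable", events = ev, duration = max(time) - min(time) +
        (time[2] - time[1]), samplingRate = 1 / (time[2] - time[1]))
}

#' Measure amplitude, rise time and decay time of one event
#'
#' Amplitude is the peak %dF/F minus a local pre-event baseline (median of
#' the `localBaselineS` seconds before onset; the global zero baseline is
#' also reported). Rise time is the interpolated 10% to 90% interval on the
#' ascending limb; decay time is the interpolated peak-to-50% interval on the
#' descending limb, flagged censored when the trace ends first.
#'
#' @param dff numeric %dF/F trace.
#' @param time numeric, seconds.
#' @param event one-row data.frame with `onset_time`, `peak_time`
#'   (as produced inside [detectEvents()]).
#' @param localBaselineS seconds of pre-onset trace the local baseline is
#'   taken over (default 1).
#' @param riseFractions,decayFraction kinetic fractions (defaults 0.1/0.9 and
#'   0.5).
#' @return list with `amplitude`, `amplitude_global`, `rise_time`,
#'   `decay_time`, `decay_censored`.
#' @export
eventKinetics <- function(dff, time, event, localBaselineS = 1,
                          riseFractions = c(0.1, 0.9), decayFraction = 0.5) {
  pk <- which.min(abs(time - event$peak_time))
  on <- which.min(abs(time - event$onset_time))
  pre <- dff[time >= event$onset_time - localBaselineS & time < event$onset_time]
  base <- if (length(pre)) stats::median(pre) else 0
  amp <- dff[pk] - base
  res <- list(amplitude = amp, amplitude_global = dff[pk],
              rise_time = NA_real_, decay_time = NA_real_,
              decay_censored = FALSE)
  if (!is.finite(amp) || amp <= 0) return(res)

  crossUp <- function(level) {
    # last upward crossing of `level` before the peak, interpolated
    seg <- on:pk
    below <- which(dff[seg] <= level)
    if (!length(below)) return(time[seg[1]])
    i <- seg[max(below)]
    if (i == pk) return(time[pk])
    t0 <- time[i]; t1 <- time[i + 1]
    y0 <- dff[i]; y1 <- dff[i + 1]
    if (y1 == y0) t1 else t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  }
  t10 <- crossUp(base + riseFractions[1] * amp)
  t90 <- crossUp(base + riseFractions[2] * amp)
  res$rise_time <- t90 - t10

  lvl <- base + decayFraction * amp
  post <- pk:length(dff)
  below <- which(dff[post] <= lvl)
  if (!length(below)) {
    res$decay_censored <- TRUE
  } else {
    i <- post[min(below)]
    if (i == pk) res$decay_time <- 0
    else {
      t0 <- time[i - 1]; t1 <- time[i]
      y0 <- dff[i - 1]; y1 <- dff[i]
      tc <- if (y1 == y0) t1 else t0 + (lvl - y0) / (y1 - y0) * (t1 - t0)
      res$decay_time <- tc - time[pk]
    }
  }
  res
}

#' Calcium transient frequency in events per minute
#'
#' Per-ROI event count divided by the recording duration, in events/min;
#' optionally averaged across the ROIs of the field of view.
#'
#' @param eventTable an [EventTable].
#' @param duration recording length in seconds.
#' @param roiIds ROI ids to report (silent ROIs get 0); defaults to the ids
#'   present in the table.
#' @param perFov if TRUE return the single FOV average instead of the per-ROI
#'   vector.
#' @return named numeric vector of events/min, or a scalar when `perFov`.
#' @export
transientFrequency <- function(eventTable, duration, roiIds = NULL,
                               perFov = FALSE) {
  if (duration <= 0) stop("duration must be positive")
  ev <- events(eventTable)
  if (is.null(roiIds)) roiIds <- sort(unique(ev$roi_id))
  n <- vapply(roiIds, function(r) sum(ev$roi_id == r), 0)
  f <- n / duration * 60
  names(f) <- as.character(roiIds)
  if (perFov) mean(f) else f
}
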