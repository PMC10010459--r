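#' Simulate per-ROI GCaMP fluorescence traces with known transients
#'
#' Generates raw fluorescence traces containing calcium transients of
#' specified amplitude and rise/decay time constants on a constant baseline,
#' with additive Gaussian noise (optionally Poisson shot noise). Each
#' transient follows a double-exponential waveform
#' \eqn{(1 - e^{-(t-t_0)/\tau_r})\, e^{-(t-t_0)/\tau_d}} scaled so its maximum
#' equals the requested fractional amplitude. The returned ground truth lists
#' every injected transient's true amplitude, onset and peak time, so event
#' detection and kinetics can be scored without real recordings.
#'
#' @param events list, one element per ROI, each a data.frame with columns
#'   `amplitude` (fractional dF/F, > 0), `rise_tau` (s), `decay_tau` (s),
#'   `onset_time` (s within the trace).
#' @param duration trace length in seconds (default 600 s, a 10 min baseline).
#' @param samplingRate Hz (default 10).
#' @param noiseSd additive Gaussian SD in fractional fluorescence units
#'   (default 0.02).
#' @param baselineF0 baseline fluorescence in arbitrary units (default 100).
#' @param shotNoise logical; if TRUE, draw each sample from a Poisson with the
#'   noiseless trace as mean instead of adding Gaussian noise.
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical output.
#' @return list with `time` (s), `traces` (samples x ROIs matrix of raw
#'   fluorescence), and `truth`, a data.frame per injected transient:
#'   `roi_id`, `amplitude_pct` (%dF/F), `onset_time`, `peak_time`,
#'   `rise_tau`, `decay_tau`.
#' @export
simTraces <- function(events, duration = 600, samplingRate = 10,
                      noiseSd = 0.02, baselineF0 = 100,
                      shotNoise = FALSE, seed = 1L) {
  stopifnot_scalar(duration, "duration")
  stopifnot_scalar(samplingRate, "samplingRate")
  stopifnot_scalar(baselineF0, "baselineF0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!is.list(events)) stop("'events' must be a list of per-ROI data.frames")
  time <- seq(0, duration - 1 / samplingRate, by = 1 / samplingRate)
  nRoi <- length(events)
  truth <- list()
  clean <- matrix(0, nrow = length(time), ncol = max(nRoi, 1))
  for (r in seq_len(nRoi)) {
    ev <- events[[r]]
    if (is.null(ev) || nrow(ev) == 0) next
    with(ev, {
      if (any(amplitude <= 0) || any(rise_tau <= 0) || any(decay_tau <= 0))
        stop("transient amplitude, rise_tau and decay_tau must be positive")
      if (any(onset_time < 0) || any(onset_time >= duration))
        stop("transient onset_time must lie within the trace duration")
    })
    sig <- numeric(length(time))
    for (k in seq_len(nrow(ev)))
      sig <- sig + ev$amplitude[k] *
        transientShape(time, ev$onset_time[k], ev$rise_tau[k], ev$decay_tau[k])
    clean[, r] <- sig
    truth[[length(truth) + 1L]] <- data.frame(
      roi_id = r,
      amplitude_pct = 100 * ev$amplitude,
      onset_time = ev$onset_time,
      peak_time = ev$onset_time + transientPeakOffset(ev$rise_tau, ev$decay_tau),
      rise_tau = ev$rise_tau, decay_tau = ev$decay_tau)
  }
  clean <- baselineF0 * (1 + clean[, seq_len(max(nRoi, 1)), drop = FALSE])
  traces <- withSeed(seed, {
    if (shotNoise) {
      matrix(stats::rpois(length(clean), lambda = pmax(clean, 0)),
             nrow = nrow(clean))
    } else if (noiseSd > 0) {
      clean + baselineF0 * matrix(stats::rnorm(length(clean), sd = noiseSd),
                                  nrow = nrow(clean))
    } else clean
  })
  colnames(traces) <- paste0("roi", seq_len(ncol(traces)))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(roi_id = integer(), amplitude_pct = numeric(),
               onset_time = numeric(), peak_time = numeric(),
               rise_tau = numeric(), decay_tau = numeric())
  list(time = time, traces = traces, truth = truth,
       params = list(duration = duration, samplingRate = samplingRate,
                     noiseSd = noiseSd, baselineF0 = baselineF0, seed = seed))
}

#' Simulate a 16-bit movie of astrocyte-shaped blobs
#'
#' Renders Gaussian-profile blobs on a constant background. Each blob's
#' spatial sigma is chosen so the area enclosed above half its peak equals the
#' requested pixel area (for a 2-D Gaussian that area is
#' \eqn{2\pi\sigma^2 \ln 2}), matching the footprint convention of the
#' segmentation size filter.
#'
#' @param blobs data.frame with columns `x`, `y` (centroid, pixel units,
#'   1-based), `area_px` (pixels above half maximum), `peak` (peak intensity
#'   above background, 16-bit counts).
#' @param dim frame size, `c(rows, cols)` (default 360 x 360, a 180 um FOV at
#'   0.5 um/px).
#' @param nFrames number of frames (blobs are static across frames).
#' @param background background level in counts (default 400).
#' @param noiseSd Gaussian read-noise SD in counts (default 0).
#' @param seed RNG seed.
#' @return integer array `dim[1] x dim[2] x nFrames`, clipped to 0..65535.
#' @export
simAstroMovie <- function(blobs, dim = c(360, 360), nFrames = 10,
                          background = 400, noiseSd = 0, seed = 1L) {
  frame <- matrix(background, dim[1], dim[2])
  if (nrow(blobs)) {
    if (any(blobs$area_px <= 0)) stop("blob areas must be positive")
    if (any(blobs$x < 1 | blobs$x > dim[1] | blobs$y < 1 | blobs$y > dim[2]))
      stop("blob centroids must lie inside the frame")
    if (any(blobs$area_px > dim[1] * dim[2]))
      stop("blob area exceeds the frame")
    xs <- seq_len(dim[1]); ys <- seq_len(dim[2])
    for (k in seq_len(nrow(blobs))) {
      sigma <- sqrt(blobs$area_px[k] / (2 * pi * log(2)))
      g <- exp(-outer((xs - blobs$x[k])^2, (ys - blobs$y[k])^2, "+") /
                 (2 * sigma^2))
      frame <- frame + blobs$peak[k] * g
    }
  }
  arr <- withSeed(seed, {
    out <- array(rep(frame, nFrames), dim = c(dim, nFrames))
    if (noiseSd > 0) out <- out + array(stats::rnorm(length(out), sd = noiseSd),
                                        dim = dim(out))
    out
  })
  storage.mode(arr) <- "double"
  arr <- round(pmin(pmax(arr, 0), 65535))
  storage.mode(arr) <- "integer"
  arr
}

#' Simulate an RBC line-scan kymograph at a known velocity
#'
#' Dark streaks of Gaussian cross-section on a bright background; the streak
#' slope in pixels per line equals `velocity * 1000 / (pixelSize * lineRate)`
#' exactly, so the radon velocimeter can be scored against ground truth.
#' Defaults emulate a 10 um bidirectional scan at ~2000 Hz.
#'
#' @param velocity RBC velocity in mm/s (sign = direction along the scan).
#' @param lineRate lines per second (default 2000 Hz).
#' @param pixelSize um per spatial pixel (default 0.1, i.e. 100 px over 10 um).
#' @param nLines number of scan lines (default 2000, one second).
#' @param extentUm spatial extent of the scan in um (default 10).
#' @param streakDensity expected streaks per line (default 0.1).
#' @param contrast streak depth as a fraction of background (default 0.5).
#' @param streakSigmaPx Gaussian cross-section sigma in px (default 1.5).
#' @param noiseSd additive Gaussian noise SD as a fraction of background.
#' @param seed RNG seed.
#' @return a [Kymograph] with attributes `velocity` (ground truth, mm/s) and
#'   `slope` (px/line) stored in `attr(, "truth")`.
#' @export
simKymograph <- function(velocity, lineRate = 2000, pixelSize = 0.1,
                         nLines = 2000, extentUm = 10, streakDensity = 0.1,
                         contrast = 0.5, streakSigmaPx = 1.5,
                         noiseSd = 0, seed = 1L) {
  stopifnot_scalar(lineRate, "lineRate")
  stopifnot_scalar(pixelSize, "pixelSize")
  nSpace <- round(extentUm / pixelSize)
  slope <- velocity * 1000 / (pixelSize * lineRate)   # px per line
  if (abs(slope) > nSpace)
    stop("velocity implies a streak slope steeper than the spatial extent per line; unresolvable")
  mat <- withSeed(seed, {
    m <- matrix(1, nSpace, nLines)
    # spawn streaks along an extended entry range so they cross the full strip
    span <- abs(slope) * nLines
    nStreak <- stats::rpois(1, streakDensity * nLines)
    x0 <- stats::runif(nStreak, 1 - span * (slope > 0), nSpace + span * (slope < 0))
    x <- seq_len(nSpace)
    tl <- seq_len(nLines) - 1
    for (k in seq_len(nStreak)) {
      ctr <- x0[k] + slope * tl
      keep <- which(ctr > -4 * streakSigmaPx & ctr < nSpace + 4 * streakSigmaPx)
      for (j in keep)
        m[, j] <- m[, j] - contrast * exp(-(x - ctr[j])^2 / (2 * streakSigmaPx^2))
    }
    if (noiseSd > 0) m <- m + matrix(stats::rnorm(length(m), sd = noiseSd),
                                     nrow = nSpace)
    m
  })
  ky <- new("Kymograph", mat = mat, pixelSize = pixelSize, lineRate = lineRate)
  attr(ky, "truth") <- list(velocity = velocity, slope = slope)
  ky
}

#' Simulate an arteriole lumen time series with a known dilation response
#'
#' A plateau response: exponential rise after stimulus onset, exponential
#' return after stimulus offset, normalized so the noiseless maximum equals
#' `baseline * (1 + dilationPct/100)` exactly.
#'
#' @param baselineLumen baseline lumen measure (area proxy, a.u.; default 100).
#' @param dilationPct peak dilation as percent of baseline (default 20;
#'   negative values are allowed and flagged as constriction).
#' @param stimOnset,stimDur stimulation onset and duration in seconds
#'   (defaults 10 and 10 s).
#' @param riseS,fallS rise and fall time constants in seconds.
#' @param frameRate frames per second (default 2).
#' @param duration total length in seconds (default 50: before, during, and
#'   30 s after stimulation).
#' @param noiseSd Gaussian noise SD as a fraction of baseline.
#' @param seed RNG seed.
#' @return list with `time`, `series`, `clean` (noiseless series) and `truth`
#'   (`max_ratio_pct`, `peak_time`, `constriction` flag).
#' @export
simVesselSeries <- function(baselineLumen = 100, dilationPct = 20,
                            stimOnset = 10, stimDur = 10, riseS = 2,
                            fallS = 5, frameRate = 2, duration = 50,
                            noiseSd = 0, seed = 1L) {
  stopifnot_scalar(frameRate, "frameRate")
  time <- seq(0, duration - 1 / frameRate, by = 1 / frameRate)
  shape <- numeric(length(time))
  up <- time >= stimOnset & time < stimOnset + stimDur
  dn <- time >= stimOnset + stimDur
  shape[up] <- 1 - exp(-(time[up] - stimOnset) / riseS)
  topv <- 1 - exp(-stimDur / riseS)
  shape[dn] <- topv * exp(-(time[dn] - stimOnset - stimDur) / fallS)
  shape <- shape / max(shape)      # noiseless max is exactly dilationPct
  clean <- baselineLumen * (1 + dilationPct / 100 * shape)
  series <- withSeed(seed, {
    if (noiseSd > 0) clean + baselineLumen * stats::rnorm(length(clean), sd = noiseSd)
    else clean
  })
  list(time = time, series = series, clean = clean,
       truth = list(max_ratio_pct = 100 + dilationPct,
                    peak_time = time[which.max(clean)],
                    constriction = dilationPct < 0))
}

#' Simulate field-potential sweeps across a stimulus series
#'
#' Each sweep contains a stimulus artifact, a fast fiber-volley (FV)
#' deflection proportional to the stimulus level, an EPSP whose initial
#' (linear) falling-phase slope follows a three-parameter Boltzmann sigmoid
#' of the FV amplitude, and, at levels at or above `psThresholdLevel`, a fast
#' population-spike notch on the EPSP recovery phase.
#'
#' @param maxResponse sigmoid maximal EPSP slope, mV/ms.
#' @param halfMaxInput sigmoid half-maximal FV amplitude, mV.
#' @param slopeFactor sigmoid slope factor, mV.
#' @param nLevels number of stimulus levels (default 12).
#' @param fvGain FV amplitude per level, mV (default 0.08).
#' @param psThresholdLevel first level carrying a population spike (use
#'   `nLevels + 1` for none).
#' @param psAmplitude notch depth in mV (default 0.3).
#' @param noiseSd additive voltage noise SD in mV.
#' @param fs sampling rate in kHz (default 10, i.e. 0.1 ms steps).
#' @param sweepMs sweep length in ms (default 60).
#' @param seed RNG seed.
#' @return list of per-level sweeps (`time_ms`, `voltage_mV`, `level`,
#'   `artifact_ms`) plus `truth` with the generating parameters and the
#'   per-level true FV amplitudes and EPSP slopes.
#' @export
simFieldSweeps <- function(maxResponse = 0.5, halfMaxInput = 0.4,
                           slopeFactor = 0.1, nLevels = 12, fvGain = 0.08,
                           psThresholdLevel = 9, psAmplitude = 0.3,
                           noiseSd = 0, fs = 10, sweepMs = 60, seed = 1L) {
  if (nLevels < 4) stop("need at least 4 stimulus levels for sigmoid fitting")
  tm <- seq(0, sweepMs, by = 1 / fs)
  artMs <- 5; fvMs <- 9; epspOn <- 14
  sweeps <- vector("list", nLevels)
  fvTrue <- fvGain * seq_len(nLevels)
  slopeTrue <- maxResponse / (1 + exp((halfMaxInput - fvTrue) / slopeFactor))
  noise <- withSeed(seed, {
    matrix(if (noiseSd > 0) stats::rnorm(length(tm) * nLevels, sd = noiseSd)
           else 0, nrow = length(tm), ncol = nLevels)
  })
  for (lv in seq_len(nLevels)) {
    v <- numeric(length(tm))
    # biphasic stimulus artifact
    v <- v + 1.5 * exp(-(tm - artMs)^2 / (2 * 0.05^2)) -
      1.0 * exp(-(tm - artMs - 0.15)^2 / (2 * 0.05^2))
    # fiber volley: fast negative gaussian
    v <- v - fvTrue[lv] * exp(-(tm - fvMs)^2 / (2 * 0.4^2))
    # EPSP: linear descent at the true slope for 4 ms, then exponential return
    m <- slopeTrue[lv]
    descent <- tm >= epspOn & tm < epspOn + 4
    v[descent] <- v[descent] - m * (tm[descent] - epspOn)
    rec <- tm >= epspOn + 4
    v[rec] <- v[rec] - m * 4 * exp(-(tm[rec] - epspOn - 4) / 8)
    if (lv >= psThresholdLevel)
      v <- v - psAmplitude * exp(-(tm - (epspOn + 7.5))^2 / (2 * 0.25^2))
    sweeps[[lv]] <- data.frame(time_ms = tm, voltage_mV = v + noise[, lv],
                               level = lv, artifact_ms = artMs)
  }
  list(sweeps = sweeps,
       truth = list(max_response = maxResponse, half_max_input = halfMaxInput,
                    slope_factor = slopeFactor, fv_amplitude = fvTrue,
                    epsp_slope = slopeTrue, ps_threshold_level = psThresholdLevel))
}

#' Simulate Y-maze arm-entry sequences with a set alternation propensity
#'
#' Markov rule: with probability `p` the next entry is the arm distinct from
#' both previous entries; otherwise the previous arm is repeated. Under this
#' rule a sliding triad is an alternation exactly when two independent
#' p-coins both succeed, so the expected alternation fraction is `p^2`
#' (returned as ground truth).
#'
#' @param nEntries number of arm entries (>= 3).
#' @param p alternation propensity in [0, 1].
#' @param seed RNG seed.
#' @return list with `entries` (character vector over A/B/C) and
#'   `expected_alternation` (analytic fraction, `p^2`).
#' @export
simArmEntries <- function(nEntries, p, seed = 1L) {
  if (nEntries < 3) stop("need at least 3 entries")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  arms <- c("A", "B", "C")
  entries <- withSeed(seed, {
    e <- character(nEntries)
    e[1] <- sample(arms, 1)
    alt <- stats::runif(nEntries) < p
    e[2] <- if (alt[2]) sample(setdiff(arms, e[1]), 1) else e[1]
    for (i in 3:nEntries) {
      e[i] <- if (alt[i]) {
        rest <- setdiff(arms, c(e[i - 1], e[i - 2]))
        if (length(rest) == 1) rest else sample(rest, 1)
      } else e[i - 1]
    }
    e
  })
  list(entries = entries, expected_alternation = p^2)
}
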