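# locate the main components of a field sweep: returns indices of the FV
# trough and the EPSP descent window, or NULLs when absent
.sweepLandmarks <- function(time_ms, v, artifact_ms) {
  dt <- time_ms[2] - time_ms[1]
  base <- mean(v[time_ms < artifact_ms - 1])
  noise <- stats::sd(v[time_ms < artifact_ms - 1])
  if (!is.finite(noise) || noise == 0) noise <- 1e-6
  # search after the artifact has settled
  post <- which(time_ms > artifact_ms + 1.5)
  x <- v[post]
  # local minima below baseline - 3 noise SD
  isMin <- diff(sign(diff(c(Inf, x, Inf)))) > 0 & x < base - 3 * noise
  mins <- post[which(isMin)]
  list(base = base, noise = noise, mins = mins, dt = dt)
}

#' Fiber-volley amplitude of a field sweep
#'
#' Baseline-to-trough amplitude of the first negative deflection after the
#' stimulus artifact, in mV. A sweep with no deflection beyond 3 noise SDs
#' returns 0 with attribute `flagged = TRUE`.
#'
#' @param sweep data.frame with `time_ms`, `voltage_mV`, `artifact_ms`.
#' @return FV amplitude (mV, positive).
#' @export
measureFv <- function(sweep) {
  lm_ <- .sweepLandmarks(sweep$time_ms, sweep$voltage_mV, sweep$artifact_ms[1])
  if (!length(lm_$mins)) {
    out <- 0; attr(out, "flagged") <- TRUE
    return(out)
  }
  # the FV is the first trough; refine to the minimum of its narrow vicinity
  i <- lm_$mins[1]
  win <- which(abs(sweep$time_ms - sweep$time_ms[i]) <= 1)
  lm_$base - min(sweep$voltage_mV[win])
}

#' Initial EPSP slope of a field sweep
#'
#' Linear-regression slope over the 20-80% segment of the EPSP falling
#' phase (from EPSP onset down to its trough), magnitude in mV/ms. The EPSP
#' is taken as the deepest trough after the fiber volley.
#'
#' @param sweep data.frame with `time_ms`, `voltage_mV`, `artifact_ms`.
#' @param segment amplitude fractions of the falling phase used for the fit
#'   (default `c(0.2, 0.8)`).
#' @return EPSP slope magnitude (mV/ms); 0 with attribute `flagged = TRUE`
#'   when no EPSP is present.
#' @export
measureEpspSlope <- function(sweep, segment = c(0.2, 0.8)) {
  tm <- sweep$time_ms; v <- sweep$voltage_mV
  lm_ <- .sweepLandmarks(tm, v, sweep$artifact_ms[1])
  if (length(lm_$mins) < 2) {
    out <- 0; attr(out, "flagged") <- TRUE
    return(out)
  }
  fvT <- tm[lm_$mins[1]]
  cand <- lm_$mins[tm[lm_$mins] > fvT + 2]
  if (!length(cand)) {
    out <- 0; attr(out, "flagged") <- TRUE
    return(out)
  }
  trough <- cand[which.min(v[cand])]
  # EPSP onset: last sample at/above baseline before the trough
  preIdx <- which(tm > fvT + 1 & tm < tm[trough])
  aboveB <- preIdx[v[preIdx] >= lm_$base - lm_$noise]
  onset <- if (length(aboveB)) max(aboveB) else preIdx[1]
  amp <- lm_$base - v[trough]
  seg <- onset:trough
  frac <- (lm_$base - v[seg]) / amp
  sel <- seg[frac >= segment[1] & frac <= segment[2]]
  if (length(sel) < 2) {
    out <- 0; attr(out, "flagged") <- TRUE
    return(out)
  }
  abs(unname(stats::coef(stats::lm(v[sel] ~ tm[sel]))[2]))
}

#' Population-spike presence in a field sweep
#'
#' A population spike is a fast negative notch interrupting the EPSP
#' recovery (return) phase. The sweep is detrended with a wide boxcar so the
#' slow EPSP shape drops out, then convolved with a unit-energy
#' notch-shaped (negative Gaussian, `notchMs` sigma) matched filter. A PS is
#' declared when the filter response dips below `k` times the robust
#' response scale of the pre-artifact baseline run through the same
#' pipeline; for a noiseless sweep a small floor relative to the EPSP
#' amplitude stands in for the noise scale.
#'
#' @param sweep data.frame with `time_ms`, `voltage_mV`, `artifact_ms`.
#' @param k detection stringency in robust noise units (default 4).
#' @param notchMs expected notch sigma in ms (default 0.25).
#' @param detrendMs detrending boxcar width in ms (default 2).
#' @return logical: population spike present.
#' @export
detectPopSpike <- function(sweep, k = 4, notchMs = 0.25, detrendMs = 2) {
  tm <- sweep$time_ms; v <- sweep$voltage_mV
  lm_ <- .sweepLandmarks(tm, v, sweep$artifact_ms[1])
  if (length(lm_$mins) < 2) return(FALSE)
  fvT <- tm[lm_$mins[1]]
  cand <- lm_$mins[tm[lm_$mins] > fvT + 2]
  if (!length(cand)) return(FALSE)
  trough <- cand[which.min(v[cand])]
  dt <- tm[2] - tm[1]
  resid <- v - .boxcar(v, max(3, round(detrendMs / dt)))
  sig <- notchMs / dt
  half <- ceiling(4 * sig)
  g <- exp(-((-half):half)^2 / (2 * sig^2))
  g <- g / sqrt(sum(g^2))
  y <- stats::filter(resid, g, sides = 2)
  # response scale of noise alone, from the pre-artifact baseline plus the
  # late tail (both flat after detrending), so the estimate is stable
  quiet <- tm < sweep$artifact_ms[1] - 1 | tm > tm[trough] + 12
  scaleY <- stats::mad(y[quiet], na.rm = TRUE)
  amp <- lm_$base - v[trough]
  floorY <- max(k * scaleY, 0.02 * amp)
  # recovery segment, clear of the trough corner's detrending skirt
  span <- which(tm > tm[trough] + 2 & tm <= tm[trough] + 10)
  span <- span[!is.na(y[span])]
  if (length(span) < 5) return(FALSE)
  any(-y[span] > floorY)
}

.boltzmann <- function(x, max_response, half_max_input, slope_factor) {
  max_response / (1 + exp((half_max_input - x) / slope_factor))
}

.fitBoltzmann <- function(x, y) {
  start <- list(max_response = 1.1 * max(y),
                half_max_input = stats::median(x),
                slope_factor = diff(range(x)) / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ max_response / (1 + exp((half_max_input - x) / slope_factor)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(par = c(max_response = NA_real_,
                                        half_max_input = NA_real_,
                                        slope_factor = NA_real_),
                                converged = FALSE))
  list(par = stats::coef(fit), converged = TRUE)
}

#' Fit a three-parameter Boltzmann sigmoid
#'
#' Least-squares fit of `y = max_response / (1 + exp((half_max_input - x) /
#' slope_factor))`, the sigmoid used for both the FV and the synaptic
#' strength curve. Initialization: `max = 1.1 * max(y)`, `half = median(x)`,
#' `slope = range(x) / 4`.
#'
#' @param x,y numeric vectors (>= 4 finite points).
#' @return list with `par` (named vector `max_response`, `half_max_input`,
#'   `slope_factor`) and `converged`.
#' @export
fitSigmoid <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4) stop("need >= 4 finite points")
  .fitBoltzmann(x[ok], y[ok])
}

#' Fit synaptic strength curves across a stimulus series
#'
#' Measures FV amplitude, EPSP slope and their ratio at every stimulus
#' level, then fits the three-parameter Boltzmann sigmoid
#' `response(x) = max / (1 + exp((half - x) / slope))` to FV vs stimulus
#' level (the FV curve) and to EPSP slope vs FV amplitude (the synaptic
#' strength curve). Derived parameters follow the standard set: maximal FV
#' amplitude, half-maximal FV and curve slope from the FV fit; maximal EPSP
#' slope and its slope factor from the synaptic fit; maximal EPSP/FV ratio
#' from the measurements; and the EPSP slope at the lowest level where a
#' population spike first appears.
#'
#' @param sweeps list of per-level sweep data.frames (`time_ms`,
#'   `voltage_mV`, `level`, `artifact_ms`).
#' @param psK population-spike detection stringency (default 4).
#' @return a [StrengthCurve]. Non-convergent fits are flagged; the raw
#'   per-level measurements are always populated.
#' @export
fitStrengthCurve <- function(sweeps, psK = 4) {
  if (length(sweeps) < 4) stop("need >= 4 stimulus levels")
  lv <- do.call(rbind, lapply(sweeps, function(s) {
    fv <- measureFv(s)
    ep <- measureEpspSlope(s)
    data.frame(level = s$level[1], fv_amplitude = as.numeric(fv),
               epsp_slope = as.numeric(ep),
               ratio = if (fv > 0) as.numeric(ep) / as.numeric(fv) else NA_real_,
               ps_present = detectPopSpike(s, k = psK))
  }))
  ok <- is.finite(lv$fv_amplitude) & is.finite(lv$epsp_slope)
  degenerate <- stats::sd(lv$epsp_slope[ok]) == 0
  fvFit <- if (degenerate) list(par = c(max_response = NA_real_,
                                        half_max_input = NA_real_,
                                        slope_factor = NA_real_), converged = FALSE)
           else .fitBoltzmann(lv$level[ok], lv$fv_amplitude[ok])
  synFit <- if (degenerate) fvFit
            else .fitBoltzmann(lv$fv_amplitude[ok], lv$epsp_slope[ok])
  psLevels <- lv$level[lv$ps_present]
  psSlope <- if (length(psLevels))
    lv$epsp_slope[lv$level == min(psLevels)] else NA_real_
  derived <- c(max_fv = unname(fvFit$par["max_response"]),
               half_max_fv = unname(fvFit$par["half_max_input"]),
               fv_curve_slope = unname(fvFit$par["slope_factor"]),
               max_epsp_slope = unname(synFit$par["max_response"]),
               syn_half_max_fv = unname(synFit$par["half_max_input"]),
               syn_curve_slope = unname(synFit$par["slope_factor"]),
               max_ratio = max(lv$ratio, na.rm = TRUE),
               ps_threshold_epsp_slope = psSlope)
  new("StrengthCurve", levels = lv, fvFit = fvFit$par, synFit = synFit$par,
      derived = derived, converged = c(fvFit$converged, synFit$converged))
}

#' Quantify long-term potentiation from an EPSP slope series
#'
#' Slopes (collected at 0.033 Hz) are normalized to the mean of the
#' pre-tetanus baseline (x100); the LTP level is the mean normalized slope
#' over the final `quantMin` minutes of the post-tetanus period.
#'
#' @param time_s sweep times in seconds.
#' @param slopes EPSP slopes (mV/ms), same length.
#' @param tetanusTime time of the 100 Hz tetanus, seconds.
#' @param baselineMin required pre-tetanus baseline, minutes (default 20).
#' @param quantMin quantification window at the end of the post period,
#'   minutes (default 10).
#' @return list with `normalized` (data.frame `time_s`, `pct_baseline`) and
#'   `ltp_pct`.
#' @export
quantifyLtp <- function(time_s, slopes, tetanusTime, baselineMin = 20,
                        quantMin = 10) {
  pre <- time_s < tetanusTime
  iv <- stats::median(diff(sort(time_s)))
  if (tetanusTime - min(time_s) + iv < baselineMin * 60 - 1e-9)
    stop(sprintf("need >= %g min of pre-tetanus baseline", baselineMin))
  if (max(time_s) - tetanusTime < quantMin * 60 - 1e-9)
    stop(sprintf("need >= %g min of post-tetanus recording", quantMin))
  f0 <- mean(slopes[pre])
  norm <- 100 * slopes / f0
  lastW <- time_s > max(time_s) - quantMin * 60
  list(normalized = data.frame(time_s = time_s, pct_baseline = norm),
       ltp_pct = mean(norm[lastW & !pre]))
}
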