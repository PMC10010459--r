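# variance of the radon projection of a (masked, centered) patch at angle
# phi (radians). Coordinates are in pixel/line units; the projection axis is
# p = x cos(phi) + t sin(phi); streaks of slope s px/line collapse to points
# when tan(phi) = -s.
.radonVariance <- function(vals, x, t, phi) {
  p <- x * cos(phi) + t * sin(phi)
  idx <- round(p)
  idx <- idx - min(idx) + 1L
  sums <- rowsum(vals, idx)
  cnts <- rowsum(rep(1, length(vals)), idx)
  stats::var(sums / cnts)
}

# deterministic symmetric grid bisection around the coarse maximum; a
# mirrored kymograph explores the mirrored grid and lands on the negated
# angle exactly (ties break toward the smaller |angle|)
.refineAngle <- function(vals, x, t, phi0, step0, tol = 0.05 * pi / 180) {
  phi <- phi0; step <- step0
  while (step > tol) {
    grid <- phi + step * seq(-1, 1, by = 0.25)
    v <- vapply(grid, function(g) .radonVariance(vals, x, t, g), 0)
    best <- which(v >= max(v) - 1e-15)
    phi <- grid[best[which.min(abs(grid[best]))]]
    step <- step / 2
  }
  phi
}

#' Radon-transform RBC velocity from a line-scan kymograph
#'
#' The kymograph is cut into time bins (default 50 ms); in each bin the
#' streak angle is found as the projection angle maximizing the variance of
#' the radon projection, on a coarse 1 degree grid over (-89, 89) degrees
#' followed by symmetric grid refinement to 0.05 degrees. The streak slope
#' `s = -tan(phi)` (px/line) converts to velocity
#' `v = s * pixelSize * lineRate / 1000` mm/s. Each bin's confidence is the
#' max/mean variance contrast over the coarse grid; bins below
#' `confidenceFloor` are flagged low-confidence, and bins whose best angle
#' sits at the grid edge (unresolvably fast streaks) are flagged saturated.
#' The estimate is invariant to affine intensity transforms of the input.
#'
#' @param kymo a [Kymograph].
#' @param binMs bin width in ms (default 50).
#' @param minLines minimum lines per bin (default 8); shorter trailing bins
#'   are skipped.
#' @param confidenceFloor variance-contrast floor (default 1.5).
#' @param smoothMs moving-average window applied afterwards (default 750 ms;
#'   `NA` to skip).
#' @return a [VelocityTrace].
#' @export
radonVelocity <- function(kymo, binMs = 50, minLines = 8,
                          confidenceFloor = 1.5, smoothMs = 750) {
  m <- kymo@mat
  nSpace <- nrow(m); nLines <- ncol(m)
  linesPerBin <- round(binMs / 1000 * kymo@lineRate)
  starts <- seq(1, nLines, by = linesPerBin)
  starts <- starts[starts + linesPerBin - 1 <= nLines |
                     nLines - starts + 1 >= minLines]
  coarse <- seq(-89, 89, by = 1) * pi / 180
  xs <- seq_len(nSpace) - (nSpace + 1) / 2
  out <- lapply(starts, function(s0) {
    cols <- s0:min(s0 + linesPerBin - 1, nLines)
    if (length(cols) < minLines) return(NULL)
    patch <- m[, cols, drop = FALSE]
    ts <- seq_along(cols) - (length(cols) + 1) / 2
    # circular mask so the projection support is orientation-independent
    R <- min(nSpace, length(cols)) / 2
    X <- matrix(xs, nSpace, length(cols))
    TT <- matrix(ts, nSpace, length(cols), byrow = TRUE)
    keep <- X^2 + TT^2 <= R^2
    vals <- patch[keep]; x <- X[keep]; t <- TT[keep]
    vv <- vapply(coarse, function(g) .radonVariance(vals, x, t, g), 0)
    best <- which(vv >= max(vv) - 1e-15)
    best <- best[which.min(abs(coarse[best]))]
    phi <- .refineAngle(vals, x, t, coarse[best], 1 * pi / 180)
    slope <- -tan(phi)
    data.frame(
      bin_center = ((s0 - 1) + length(cols) / 2) / kymo@lineRate,
      velocity = slope * kymo@pixelSize * kymo@lineRate / 1000,
      confidence = max(vv) / mean(vv),
      low_confidence = max(vv) / mean(vv) < confidenceFloor,
      saturated = best <= 1 || best >= length(coarse) ||
        abs(slope) > nSpace)
  })
  bins <- do.call(rbind, out)
  vt <- new("VelocityTrace", bins = bins, binWidth = binMs / 1000,
            smoothWindow = NA_real_)
  if (is.finite(smoothMs)) vt <- smoothVelocity(vt, smoothMs) else {
    vt@bins$smoothed <- NA_real_
  }
  vt
}

#' Centered moving-average smoothing of a velocity trace
#'
#' A centered boxcar of `windowMs` (rounded to an odd number of bins; 15
#' bins for the default 750 ms over 50 ms bins) with edge truncation: near
#' the edges the effective window shrinks to the available bins, so interior
#' bins preserve the series mean.
#'
#' @param trace a [VelocityTrace].
#' @param windowMs window width in ms (default 750).
#' @return the trace with its `smoothed` column (and `smoothWindow`) set.
#' @export
smoothVelocity <- function(trace, windowMs = 750) {
  b <- trace@bins
  k <- round(windowMs / 1000 / trace@binWidth)
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  n <- nrow(b)
  b$smoothed <- vapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    mean(b$velocity[w])
  }, 0)
  trace@bins <- b
  trace@smoothWindow <- k * trace@binWidth
  trace
}

#' Stimulus-response metrics on a smoothed velocity trace
#'
#' Baseline is the mean smoothed velocity before stimulus onset; the maximum
#' change from baseline is `(max within the stimulation + post window -
#' baseline) / baseline`, and the time to maximum is measured from stimulus
#' onset. Low-confidence and saturated bins are excluded.
#'
#' @param trace a smoothed [VelocityTrace].
#' @param stimWindow `(onset, end)` seconds.
#' @param postS seconds past stimulation included in the search (default 10).
#' @return list with `baseline` (mm/s), `max_change` (fraction of baseline)
#'   and `time_to_max` (s).
#' @export
velocityMetrics <- function(trace, stimWindow, postS = 10) {
  b <- trace@bins
  ok <- !b$low_confidence & !b$saturated
  pre <- b$smoothed[ok & b$bin_center < stimWindow[1]]
  if (!length(pre) || mean(pre) <= 0)
    stop("baseline velocity must be positive")
  base <- mean(pre)
  inW <- ok & b$bin_center >= stimWindow[1] &
    b$bin_center <= stimWindow[2] + postS
  if (!any(inW)) stop("no usable bins in the stimulation window")
  i <- which(inW)[which.max(b$smoothed[inW])]
  list(baseline = base,
       max_change = (b$smoothed[i] - base) / base,
       time_to_max = b$bin_center[i] - stimWindow[1])
}
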