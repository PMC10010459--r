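test_that("fiber volley amplitude is baseline-to-trough and linear in gain", {
  tm <- seq(0, 60, by = 0.1)
  v <- numeric(length(tm)) - 0.4 * exp(-(tm - 9)^2 / (2 * 0.4^2))
  sw <- data.frame(time_ms = tm, voltage_mV = v, level = 1, artifact_ms = 5)
  expect_equal(as.numeric(measureFv(sw)), 0.4, tolerance = 1e-6)

  flat <- data.frame(time_ms = tm, voltage_mV = rep(0, length(tm)),
                     level = 1, artifact_ms = 5)
  f <- measureFv(flat)
  expect_equal(as.numeric(f), 0)
  expect_true(attr(f, "flagged"))

  fp <- simFieldSweeps(noiseSd = 0)
  fv <- vapply(fp$sweeps, measureFv, 0)
  expect_gt(cor(fv, fp$truth$fv_amplitude), 0.999)
})

test_that("EPSP slopes re-measured from noiseless sweeps sit on the sigmoid", {
  fp <- simFieldSweeps(noiseSd = 0)
  sl <- vapply(fp$sweeps, measureEpspSlope, 0)
  expect_true(all(abs(sl - fp$truth$epsp_slope) / fp$truth$epsp_slope < 0.01))

  tm <- seq(0, 60, by = 0.1)
  flat <- data.frame(time_ms = tm, voltage_mV = rep(0, length(tm)),
                     level = 1, artifact_ms = 5)
  s <- measureEpspSlope(flat)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "flagged"))
})

test_that("population spike detection keys on the recovery-phase notch", {
  fp <- simFieldSweeps(psThresholdLevel = 9, noiseSd = 0)
  ps <- vapply(fp$sweeps, detectPopSpike, TRUE)
  expect_identical(which(ps), 9:12)

  # notch 5x the noise is seen, notch 0.5x the noise is not
  noise <- 0.05
  hits <- falses <- c()
  for (s in 1:5) {
    hi <- simFieldSweeps(psThresholdLevel = 9, psAmplitude = 5 * noise,
                         noiseSd = noise, seed = s)
    lo <- simFieldSweeps(psThresholdLevel = 9, psAmplitude = 0.5 * noise,
                         noiseSd = noise, seed = s)
    hits <- c(hits, vapply(hi$sweeps[9:12], detectPopSpike, TRUE))
    falses <- c(falses, vapply(hi$sweeps[1:8], detectPopSpike, TRUE),
                vapply(lo$sweeps, detectPopSpike, TRUE))
  }
  expect_gte(mean(hits), 0.9)
  expect_lte(mean(falses), 0.05)

  # stringency: PS threshold level is non-decreasing in k
  th <- function(k) {
    p <- vapply(hi$sweeps, detectPopSpike, TRUE, k = k)
    if (any(p)) min(which(p)) else length(p) + 1
  }
  ks <- c(2, 4, 8, 16)
  expect_true(all(diff(vapply(ks, th, 0)) >= 0))
})

test_that("strength curve fit recovers generating sigmoid parameters", {
  fp <- simFieldSweeps(maxResponse = 0.5, halfMaxInput = 0.4,
                       slopeFactor = 0.1, noiseSd = 0)
  sc <- fitStrengthCurve(fp$sweeps)
  par <- curveParameters(sc)
  expect_equal(unname(par["max_epsp_slope"]), 0.5, tolerance = 0.01)
  expect_equal(unname(par["syn_half_max_fv"]), 0.4, tolerance = 0.01)
  expect_equal(unname(par["syn_curve_slope"]), 0.1, tolerance = 0.01)
  lv <- strengthLevels(sc)
  expect_equal(lv$ratio, lv$epsp_slope / lv$fv_amplitude)
  expect_equal(unname(par["ps_threshold_epsp_slope"]), lv$epsp_slope[9])

  # all-equal responses: degenerate, flagged, raw points still there
  tm <- seq(0, 60, by = 0.1)
  same <- lapply(1:6, function(l)
    data.frame(time_ms = tm,
               voltage_mV = -0.3 * exp(-(tm - 9)^2 / 0.32) -
                 0.2 * pmax(0, pmin((tm - 14) / 4, exp(-(tm - 18) / 8))),
               level = l, artifact_ms = 5))
  scd <- fitStrengthCurve(same)
  expect_false(scd@converged[2])
  expect_identical(nrow(strengthLevels(scd)), 6L)
})

test_that("sigmoid fitting tolerates measurement noise", {
  x <- 0.08 * (1:12)
  y0 <- 0.5 / (1 + exp((0.4 - x) / 0.1))
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    f <- fitSigmoid(x, y0 + rnorm(12, sd = 0.05 * 0.5))
    abs(f$par["half_max_input"] - 0.4) / 0.4
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("LTP normalizes to the pre-tetanus baseline", {
  tt <- seq(30, 50 * 60, by = 30)
  base <- rep(2, sum(tt <= 20 * 60))
  post <- rep(3, sum(tt > 20 * 60))
  r <- quantifyLtp(tt, c(base, post), tetanusTime = 20 * 60)
  expect_equal(r$ltp_pct, 150)
  expect_equal(mean(r$normalized$pct_baseline[tt <= 20 * 60]), 100)

  rflat <- quantifyLtp(tt, rep(2, length(tt)), tetanusTime = 20 * 60)
  expect_equal(rflat$ltp_pct, 100)
  # the final 10 min at 0.033 Hz holds 20 sweeps
  expect_equal(sum(tt > max(tt) - 600), 20)
  expect_error(quantifyLtp(tt[tt < 1500], rep(1, sum(tt < 1500)), 20 * 60),
               "post-tetanus")
  expect_error(quantifyLtp(tt[tt > 900], rep(1, sum(tt > 900)), 20 * 60),
               "pre-tetanus")
})

test_that("EPSP/FV ratio is invariant to uniform voltage gain", {
  fp <- simFieldSweeps(noiseSd = 0)
  sw <- fp$sweeps[[6]]
  r1 <- measureEpspSlope(sw) / measureFv(sw)
  sw2 <- sw; sw2$voltage_mV <- 2.5 * sw$voltage_mV
  r2 <- measureEpspSlope(sw2) / measureFv(sw2)
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-9)
})
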