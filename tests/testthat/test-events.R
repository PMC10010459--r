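test_that("dF/F normalization is exact and scale-invariant", {
  tm <- seq(0, 9.9, by = 0.1)
  expect_true(all(computeDff(rep(7, 100), tm, c(0, 5)) == 0))
  tr <- c(rep(100, 50), rep(150, 50))
  expect_equal(max(computeDff(tr, tm, c(0, 5))), 50)
  set.seed(1)
  tr2 <- 100 + cumsum(rnorm(100))
  expect_equal(as.numeric(computeDff(tr2 * 3.7, tm, c(0, 5))),
               as.numeric(computeDff(tr2, tm, c(0, 5))))
  expect_error(computeDff(rep(-5, 100), tm, c(0, 5)), "dead ROI")
})

test_that("event detection finds injected transients and nothing else", {
  sim <- simTraces(list(data.frame(amplitude = 0.8, rise_tau = 2,
                                   decay_tau = 6, onset_time = 60)),
                   duration = 180, samplingRate = 10, noiseSd = 0, seed = 1)
  tm <- sim$time
  dff <- computeDff(sim$traces[, 1], tm, c(0, 50))
  # noiseless baseline SD is 0: inject a tiny known jitter into the baseline
  flat <- detectEvents(rep(0, length(tm)) + 1e-9 * sin(tm), tm, c(0, 50))
  expect_identical(nrow(events(flat)), 0L)

  sim2 <- simTraces(list(data.frame(amplitude = 0.8, rise_tau = 2,
                                    decay_tau = 6, onset_time = 60)),
                    duration = 180, samplingRate = 10, noiseSd = 0.01, seed = 3)
  dff2 <- computeDff(sim2$traces[, 1], tm, c(0, 50))
  et <- events(detectEvents(dff2, tm, c(0, 50)))
  expect_identical(nrow(et), 1L)
  expect_lt(abs(et$peak_time - sim2$truth$peak_time), 0.5)
  expect_equal(et$amplitude, 80, tolerance = 0.05)

  # threshold monotonicity: stricter kSd never finds more events
  n2 <- nrow(events(detectEvents(dff2, tm, c(0, 50), kSd = 2)))
  n3 <- nrow(events(detectEvents(dff2, tm, c(0, 50), kSd = 3)))
  expect_lte(n3, n2)
  expect_error(detectEvents(rep(NA_real_, 100), tm[1:100], c(0, 5)), "all-NA")
})

test_that("every reported event clears its threshold and separation", {
  specs <- list(data.frame(amplitude = c(0.5, 0.9, 0.7),
                           rise_tau = c(1, 2, 1.5), decay_tau = c(4, 6, 5),
                           onset_time = c(30, 80, 130)))
  for (s in 1:5) {
    sim <- simTraces(specs, duration = 180, samplingRate = 10,
                     noiseSd = 0.02, seed = s)
    dff <- computeDff(sim$traces[, 1], sim$time, c(0, 25))
    ev <- events(detectEvents(dff, sim$time, c(0, 25), minDuration = 2))
    expect_true(all(ev$peak_value > ev$threshold))
    if (nrow(ev) > 1)
      expect_true(all(diff(sort(ev$peak_time)) >= 1))
  }
})

test_that("kinetics match closed forms on ramp and exponential", {
  dt <- 0.01
  # linear ramp 0 -> A over T = 2 s: 10-90% rise = 0.8 T
  tm <- seq(0, 4, by = dt)
  ramp <- pmin(pmax(tm - 1, 0) / 2, 1) * 40
  k <- eventKinetics(ramp, tm, data.frame(onset_time = 1, peak_time = 3))
  expect_equal(k$rise_time, 0.8 * 2, tolerance = dt / (0.8 * 2))
  # exponential decay with tau: half-decay = tau ln 2
  tau <- 1.5
  tm2 <- seq(0, 10, by = dt)
  expdec <- 50 * exp(-pmax(tm2 - 2, 0) / tau)
  k2 <- eventKinetics(expdec, tm2, data.frame(onset_time = 0, peak_time = 2))
  expect_equal(k2$decay_time, tau * log(2), tolerance = dt / (tau * log(2)))
  # censoring when the trace ends before the 50% point
  late <- 50 * pmin(pmax((tm2 - 9) / 0.5, 0), 1) * exp(-pmax(tm2 - 9.5, 0) / 10)
  short <- eventKinetics(late, tm2, data.frame(onset_time = 9, peak_time = 9.5))
  expect_true(short$decay_censored)
})

test_that("amplitude recovery on seeded synthetic transients is accurate", {
  res <- eventRecovery(40)
  expect_gte(res$sensitivity, 0.95)
  expect_lte(res$false_frac, 0.05)
  expect_lt(res$median_amp_err, 0.05)
})

test_that("transient frequency is a plain count-over-time", {
  et <- makeEventTable(data.frame(roi_id = rep(1L, 10),
                                  onset_time = seq(10, 550, length.out = 10),
                                  peak_time = seq(11, 551, length.out = 10)),
                       duration = 600)
  expect_equal(unname(transientFrequency(et, 600)), 1.0)
  empty <- makeEventTable(data.frame(roi_id = integer(), onset_time = numeric(),
                                     peak_time = numeric()))
  expect_equal(transientFrequency(empty, 600, roiIds = 1), c("1" = 0))

  set.seed(8)
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    ids <- sample(1:4, n, replace = TRUE)
    on <- runif(n, 0, 500)
    et2 <- makeEventTable(data.frame(roi_id = ids, onset_time = on,
                                     peak_time = on + runif(n, 0.1, 2)))
    f <- transientFrequency(et2, 500, roiIds = 1:4)
    for (r in 1:4) expect_equal(unname(f[r]), sum(ids == r) / 500 * 60)
  }
})
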