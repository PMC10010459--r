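test_that("trace generator is deterministic and honest about its ground truth", {
  ev <- list(data.frame(amplitude = 0.5, rise_tau = 2, decay_tau = 6,
                        onset_time = 20))
  a <- simTraces(ev, duration = 60, samplingRate = 10, noiseSd = 0.02, seed = 7)
  b <- simTraces(ev, duration = 60, samplingRate = 10, noiseSd = 0.02, seed = 7)
  expect_identical(a$traces, b$traces)

  # no signal, no noise: constant at the baseline, empty truth
  flat <- simTraces(list(data.frame(amplitude = numeric(), rise_tau = numeric(),
                                    decay_tau = numeric(), onset_time = numeric())),
                    duration = 10, samplingRate = 10, noiseSd = 0, baselineF0 = 100)
  expect_true(all(flat$traces == 100))
  expect_identical(nrow(flat$truth), 0L)

  # the injected waveform really peaks at the stated amplitude and time
  clean <- simTraces(ev, duration = 60, samplingRate = 100, noiseSd = 0, seed = 1)
  expect_equal(max(clean$traces[, 1]), 100 * 1.5, tolerance = 1e-4)
  expect_equal(clean$time[which.max(clean$traces[, 1])], clean$truth$peak_time,
               tolerance = 0.02)

  # mean of true peak amplitudes across many transients
  many <- lapply(1:100, function(i)
    data.frame(amplitude = 0.5, rise_tau = 2, decay_tau = 6,
               onset_time = seq(5, 500, length.out = 10)))
  truth <- simTraces(many, duration = 520, samplingRate = 2, noiseSd = 0)$truth
  expect_equal(nrow(truth), 1000L)
  expect_equal(mean(truth$amplitude_pct) / 100, 0.5, tolerance = 0.01)
})

test_that("blob movie renders the requested half-maximum footprint", {
  mv <- simAstroMovie(data.frame(x = 180, y = 180, area_px = 1000, peak = 3000),
                      nFrames = 1, background = 400, noiseSd = 0)
  fr <- mv[, , 1]
  expect_equal(sum(fr > 400 + 1500), 1000, tolerance = 0.05)

  empty <- simAstroMovie(data.frame(x = numeric(), y = numeric(),
                                    area_px = numeric(), peak = numeric()),
                         nFrames = 2, background = 400)
  expect_true(all(empty == 400))

  two <- simAstroMovie(data.frame(x = c(90, 270), y = c(90, 270),
                                  area_px = c(1000, 1000), peak = c(3000, 3000)),
                       nFrames = 1)[, , 1]
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((two > 400 + 1500) * 1)))
  expect_equal(max(lab), 2)

  expect_error(simAstroMovie(data.frame(x = 500, y = 10, area_px = 1000,
                                        peak = 100)), "inside the frame")
  expect_error(simAstroMovie(data.frame(x = 10, y = 10, area_px = 1e9,
                                        peak = 100)), "exceeds the frame")
})

test_that("kymograph streak slope follows the unit conversion exactly", {
  ky <- simKymograph(1.0, lineRate = 2000, pixelSize = 0.1, nLines = 100, seed = 1)
  expect_equal(attr(ky, "truth")$slope, 5)   # 1000 um/s / (0.1 um x 2000 Hz)

  still <- simKymograph(0, nLines = 50, seed = 2)
  m <- still@mat
  expect_true(all(apply(m, 1, function(r) diff(range(r))) < 1e-12))

  expect_error(simKymograph(50, lineRate = 2000, pixelSize = 0.1, nLines = 10),
               "unresolvable")
  expect_identical(simKymograph(2, seed = 9)@mat, simKymograph(2, seed = 9)@mat)
})

test_that("vessel series generator produces the stated plateau response", {
  flat <- simVesselSeries(dilationPct = 0, noiseSd = 0)
  expect_true(all(abs(flat$series - flat$series[1]) < 1e-12))

  v <- simVesselSeries(dilationPct = 20, noiseSd = 0)
  expect_equal(v$truth$max_ratio_pct, 120)
  expect_equal(100 * max(v$clean) / min(v$clean), 120, tolerance = 1e-10)
  expect_equal(v$time[which.max(v$clean)], v$truth$peak_time)

  con <- simVesselSeries(dilationPct = -10, noiseSd = 0)
  expect_true(con$truth$constriction)
})

test_that("field sweep generator is linear in gain and notch-free below threshold", {
  a <- simFieldSweeps(fvGain = 0.08, noiseSd = 0, seed = 1)
  b <- simFieldSweeps(fvGain = 0.16, noiseSd = 0, seed = 1)
  fvA <- vapply(a$sweeps, measureFv, 0)
  fvB <- vapply(b$sweeps, measureFv, 0)
  expect_equal(fvB, 2 * fvA, tolerance = 1e-6)

  none <- simFieldSweeps(psThresholdLevel = 13, noiseSd = 0)
  expect_false(any(vapply(none$sweeps, detectPopSpike, TRUE)))
})

test_that("arm-entry generator hits its analytic alternation expectation", {
  expect_equal(percentAlternation(simArmEntries(50, p = 1, seed = 1)$entries), 100)
  expect_equal(percentAlternation(simArmEntries(50, p = 0, seed = 1)$entries), 0)
  g <- simArmEntries(10000, p = 0.5, seed = 42)
  expect_equal(g$expected_alternation, 0.25)
  expect_equal(percentAlternation(g$entries) / 100, g$expected_alternation,
               tolerance = 0.02 / 0.25)
})
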