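test_that("binarization uses half-open bins at the configured rate", {
  empty <- makeEventTable(data.frame(roi_id = integer(), onset_time = numeric(),
                                     peak_time = numeric()), duration = 60)
  r <- binarizeEvents(empty, roiIds = 1:3)
  expect_identical(dim(rasterMatrix(r)), c(3L, 120L))
  expect_true(all(rasterMatrix(r) == 0))

  # an event spanning 10.2-10.7 s touches exactly the bins [10,10.5) and [10.5,11)
  et <- makeEventTable(data.frame(roi_id = 1L, onset_time = 10.2,
                                  peak_time = 10.4, span_start = 10.2,
                                  span_end = 10.7), duration = 60)
  m <- rasterMatrix(binarizeEvents(et, roiIds = 1))
  expect_identical(which(m[1, ] == 1L), 21:22)

  expect_error(binarizeEvents(et, roiIds = 1, window = c(30, 120)),
               "outside the recording")
})

test_that("pair correlation equals the direct Pearson formula", {
  r <- makeRaster(rbind(c(1, 0, 1, 0, 1, 0), c(1, 0, 1, 0, 1, 0)))
  expect_equal(pairCC(r, 1, 2), 1.0)
  r2 <- makeRaster(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
  expect_equal(pairCC(r2, 1, 2), -1.0)
  expect_warning(cc <- pairCC(makeRaster(rbind(rep(0, 6), c(1, 0, 1, 0, 1, 0))),
                              1, 2), "constant")
  expect_true(is.na(cc))

  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(rbinom(2 * 40, 1, 0.3), nrow = 2)
    if (sd(m[1, ]) == 0 || sd(m[2, ]) == 0) next
    x <- m[1, ]; y <- m[2, ]
    brute <- mean((x - mean(x)) * (y - mean(y))) /
      (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
    expect_equal(pairCC(makeRaster(m), 1, 2), brute, tolerance = 1e-12)
  }
})

test_that("weighted cc scales by the pair's event-sample fraction of 240", {
  # identical rows with 12 event bins each: cc = 1, 24/240 = 0.1
  row <- rep(0, 120); row[seq(1, 112, by = 10)] <- 1
  expect_equal(sum(row), 12)
  r <- makeRaster(rbind(row, row))
  expect_equal(weightedCC(1.0, r, 1, 2), 0.1)
  expect_equal(weightedCC(0.5, makeRaster(matrix(0L, 2, 120) + 0), 1, 2), 0)

  # |wcc| <= |cc| on random rasters
  set.seed(9)
  for (rep in 1:20) {
    m <- matrix(rbinom(2 * 120, 1, runif(1, 0.05, 0.5)), nrow = 2)
    if (sd(m[1, ]) == 0 || sd(m[2, ]) == 0) next
    cc <- pairCC(makeRaster(m), 1, 2)
    expect_lte(abs(weightedCC(cc, makeRaster(m), 1, 2)), abs(cc) + 1e-15)
  }
})

test_that("pair inclusion is strict at wcc > 0.02", {
  mk <- function(k) {            # identical rows with k event bins each
    row <- rep(0, 120); row[seq_len(k) * 3] <- 1
    makeRaster(rbind(row, row))
  }
  # 2 bins each: wcc = 4/240 = 0.0167 -> excluded; 3 bins: 6/240 = 0.025 -> included
  expect_false(pairTable(buildPairNetwork(mk(2)))$included)
  expect_true(pairTable(buildPairNetwork(mk(3)))$included)
  # exactly at the threshold: excluded (strict >)
  p <- pairTable(buildPairNetwork(mk(3), wccMin = 0.025))
  expect_false(p$included)
})

test_that("planted coactive cliques are recovered exactly", {
  set.seed(21)
  nRoi <- 12; nBin <- 120
  m <- matrix(0L, nRoi, nBin)
  # two planted cliques firing in identical bins, plus silent-ish others
  for (cl in list(1:3, 4:7)) {
    bins <- sample(nBin, 10)
    for (r in cl) m[r, bins] <- 1L
  }
  for (r in 8:12) m[r, sample(nBin, 2)] <- 1L   # sparse uncorrelated singles
  net <- buildPairNetwork(makeRaster(m))
  p <- pairTable(net)
  planted <- choose(3, 2) + choose(4, 2)
  expect_identical(sum(p$included), as.integer(planted))
  # weighted cc equals hand-computed cc x events/240 at machine precision
  for (k in which(p$included)) {
    i <- p$roi_i[k]; j <- p$roi_j[k]
    hand <- cor(m[i, ], m[j, ]) * (sum(m[i, ]) + sum(m[j, ])) / 240
    expect_equal(p$wcc[k], hand, tolerance = 1e-12)
  }
})

test_that("FOV summary computes densities and applies the strict gate", {
  row <- rep(0, 120); row[3 * (1:20)] <- 1
  r <- makeRaster(rbind(row, row))
  net <- buildPairNetwork(r, distances = data.frame(roi_i = 1, roi_j = 2,
                                                    distance_um = 40))
  s <- networkSummary(net, fovAreaMm2 = 0.0324)
  expect_equal(s$coactive_pairs_per_mm2, 1 / 0.0324, tolerance = 1e-6)
  expect_equal(s$mean_pair_distance_um, 40)

  # density exactly at 100 correlated ROIs per mm^2 is excluded (strict >)
  s2 <- networkSummary(net, fovAreaMm2 = 2 / 100)
  expect_equal(s2$correlated_rois_per_mm2, 100)
  expect_false(s2$fov_included)
  s3 <- networkSummary(net, fovAreaMm2 = 0.0199)
  expect_true(s3$fov_included)

  # no events anywhere: zero coactive connections, flagged
  e <- makeRaster(matrix(0L, 3, 120))
  nete <- suppressWarnings(buildPairNetwork(e))
  se <- networkSummary(nete, fovAreaMm2 = 0.0324)
  expect_equal(se$coactive_pairs_per_mm2, 0)
  expect_true(se$zero_pairs)
})

test_that("active ROI density and oscillation frequency count correctly", {
  et <- makeEventTable(data.frame(roi_id = 1:10, onset_time = 1:10,
                                  peak_time = 1:10 + 0.5), duration = 60)
  expect_equal(activeRoiDensity(et, 0.0324), 10 / 0.0324)
  empty <- makeEventTable(data.frame(roi_id = integer(), onset_time = numeric(),
                                     peak_time = numeric()))
  expect_equal(activeRoiDensity(empty, 0.0324), 0)
  # additivity: one more active ROI adds exactly 1/area
  et2 <- makeEventTable(data.frame(roi_id = 1:11, onset_time = 1:11,
                                   peak_time = 1:11 + 0.5), duration = 60)
  expect_equal(activeRoiDensity(et2, 0.0324) - activeRoiDensity(et, 0.0324),
               1 / 0.0324)

  stim <- makeEventTable(data.frame(roi_id = c(1, 1), onset_time = c(2, 6),
                                    peak_time = c(2.5, 6.5)), duration = 60)
  expect_equal(oscillationFrequency(stim, c(0, 10)), 0.2)
  expect_equal(oscillationFrequency(empty, c(0, 10)), 0)
})

test_that("correlogram node weights are row sums of included wcc", {
  row <- rep(0, 120); row[3 * (1:20)] <- 1
  net <- buildPairNetwork(makeRaster(rbind(row, row)))
  cg <- exportCorrelogram(net)
  expect_equal(cg$nodes$weight, rep(pairTable(net)$wcc, 2))

  set.seed(13)
  m <- matrix(rbinom(6 * 120, 1, 0.2), nrow = 6)
  net2 <- suppressWarnings(buildPairNetwork(makeRaster(m)))
  cg2 <- exportCorrelogram(net2)
  p <- pairTable(net2); inc <- p[p$included, ]
  for (id in cg2$nodes$id)
    expect_equal(cg2$nodes$weight[cg2$nodes$id == id],
                 sum(inc$wcc[inc$roi_i == id | inc$roi_j == id]))
  expect_true(all(cg2$edges$cc >= 0.4))
})
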