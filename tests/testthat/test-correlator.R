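# Direct and multi-tau correlators.

test_that("a constant trace has G = 1 at all lags", {
  tr <- photonTrace(1e-5, rep(5L, 5000), rep(3L, 5000))
  cv <- correlateDirect(tr, "green-auto", maxLag = 20e-5)
  expect_true(all(abs(gValues(cv) - 1) < 1e-12))
  cvx <- correlateMultitau(tr, "cross", blocks = 3)
  expect_true(all(abs(gValues(cvx) - 1) < 1e-12))
})

test_that("independent Poisson channels show no cross-correlation", {
  set.seed(42)
  n <- 2e5
  tr <- photonTrace(1e-5, rpois(n, 5), rpois(n, 5))
  cv <- correlateDirect(tr, "cross", maxLag = 20e-5)
  # per-lag standard error for independent Poisson at these rates
  se <- sqrt(5 * 5 * (1 + 5 + 5) / n) / (5 * 5)
  expect_true(all(abs(gValues(cv) - 1) < 3.5 * se))
  expect_lt(abs(mean(gValues(cv)) - 1), 3 * se / sqrt(length(gValues(cv))) * 3)
})

test_that("zero-signal channels are rejected", {
  tr <- photonTrace(1e-5, rep(0L, 1000), rep(2L, 1000))
  expect_error(correlateDirect(tr, "green-auto", maxLag = 5e-5),
               "channel has no signal")
  expect_error(correlateMultitau(tr, "cross"), "channel has no signal")
})

test_that("max lag beyond a tenth of the duration is rejected", {
  tr <- photonTrace(1e-5, rep(2L, 1000), rep(2L, 1000))
  expect_error(correlateDirect(tr, "green-auto", maxLag = 2e-3),
               "duration / 10")
})

test_that("simulated single-species amplitude matches the model prediction", {
  count <- 80
  sp <- speciesSpec("m", countMean = count, D = fastD(), brightnessGreen = 3e4)
  tr <- simTrace(sp, seed = 51, duration = 3)
  cv <- correlateDirect(tr, "green-auto", maxLag = 40e-5)
  nEff <- expectedN(count)
  model <- oracleAuto(lags(cv)[1], nEff, 0, 5e-6, 1, 7e-4, 7e-4, 5)
  expect_lt(abs((gValues(cv)[1] - 1) - (model - 1)) / (model - 1), 0.2)
})

test_that("multi-tau agrees with the direct oracle", {
  sp <- speciesSpec("m", countMean = 40, D = fastD(), brightnessGreen = 3e4)
  tr <- simTrace(sp, seed = 61, duration = 1)
  m <- 16L
  mt <- correlateMultitau(tr, "green-auto", channelsPerBlock = m, blocks = 5)

  # first block: identical arithmetic, exact agreement
  dr <- correlateDirect(tr, "green-auto", maxLag = (m + 1) * tr@binWidth)
  expect_lt(max(abs(gValues(mt)[1:m] - gValues(dr)[1:m])), 1e-10)

  # rebinned blocks: exact agreement with the direct estimator applied to the
  # explicitly rebinned trace
  rebin2 <- function(v) {
    n2 <- length(v) %/% 2L
    v[seq(1, 2 * n2, 2)] + v[seq(2, 2 * n2, 2)]
  }
  g2 <- rebin2(as.numeric(tr@countsGreen))
  tr2 <- photonTrace(2 * tr@binWidth, g2, rebin2(as.numeric(tr@countsRed)))
  dr2 <- correlateDirect(tr2, "green-auto", maxLag = (m + 1) * tr2@binWidth)
  blk2 <- gValues(mt)[(m + 1):(m + m / 2)]
  expect_lt(max(abs(blk2 - gValues(dr2)[(m / 2 + 1):m])), 1e-10)
})

test_that("rebinned lags track the un-rebinned correlation of a smooth trace", {
  # deterministic, slowly varying trace: rebinning bias must stay below 1e-3
  t <- seq(0, 1, by = 1e-4)
  counts <- as.integer(round(50 + 20 * sin(2 * pi * t / 0.05)))
  tr <- photonTrace(1e-4, counts, counts)
  mt <- correlateMultitau(tr, "green-auto", channelsPerBlock = 16, blocks = 4)
  dr <- correlateDirect(tr, "green-auto", maxLag = max(lags(mt)) + 2e-4)
  idx <- match(round(lags(mt) / 1e-4), round(lags(dr) / 1e-4))
  relDiff <- abs(gValues(mt) - gValues(dr)[idx]) / gValues(dr)[idx]
  expect_lt(max(relDiff), 1e-3)
})

test_that("the multi-tau grid spans the documented quasi-logarithmic range", {
  # 16 channels/block, 8 blocks, 1 us bins: lags from 1 us to ~2 ms
  set.seed(7)
  tr <- photonTrace(1e-6, rpois(2^13, 3), rpois(2^13, 3))
  mt <- correlateMultitau(tr, "green-auto", channelsPerBlock = 16, blocks = 8)
  expect_equal(min(lags(mt)), 1e-6)
  expect_equal(max(lags(mt)), 16 * 2^7 * 1e-6)  # 2.048 ms
  expect_true(all(diff(lags(mt)) > 0))
})

test_that("split-and-average estimates per-lag spread and stays near the full curve", {
  sp <- speciesSpec("m", countMean = 60, D = fastD(), brightnessGreen = 3e4)
  tr <- simTrace(sp, seed = 71, duration = 4)
  avg <- splitAndAverage(tr, nSegments = 10, pair = "green-auto",
                         method = "multitau", blocks = 4)
  expect_true(all(is.finite(sdValues(avg))))
  expect_true(any(sdValues(avg) > 0))

  full <- correlateMultitau(tr, "green-auto", blocks = 4)
  idx <- match(round(lags(avg) / tr@binWidth), round(lags(full) / tr@binWidth))
  sdMean <- pmax(sdValues(avg) / sqrt(10), 1e-6)
  expect_true(all(abs(gValues(avg) - gValues(full)[idx]) < 4 * sdMean))

  expect_error(splitAndAverage(tr, nSegments = nBins(tr), pair = "green-auto"),
               "fewer than 4 bins")
})

test_that("long stationary traces decorrelate to baseline at large lags", {
  sp <- speciesSpec("fast", countMean = 20, D = 50, brightnessGreen = 4e4)
  tr <- suppressWarnings(simulatePhotonTrace(
    sp, testVolume(),
    simulationConfig(boxDimensions = c(1.2, 1.2, 5), timeStep = 5e-5,
                     duration = 60, binWidth = 5e-5, seed = 81)))
  mt <- correlateMultitau(tr, "green-auto", blocks = 16)
  lg <- lags(mt)
  tail <- gValues(mt)[lg >= max(lg) / 10]
  expect_lt(abs(mean(tail) - 1), 0.01)

  # and the smallest lag always exceeds baseline for a fluctuating species
  expect_gt(gValues(mt)[1], 1)
})
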