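# Derived statistics: calibration, DNA-bound diffusion, RCA, CPM, bound
# fraction and group comparison.

test_that("reference-dye calibration reproduces the volume geometry", {
  dye <- autoFit(N = 2, F1 = 1, tauD1 = 25e-6, tauD2 = 25e-6, S = 5,
                 fixed = "F1", converged = TRUE)
  cal <- calibrateVolume(dye, dyeD = 400, dyeLabel = "ATTO488")
  expect_equal(cal@omega, 0.2, tolerance = 1e-15)
  expect_equal(cal@z0, 1.0, tolerance = 1e-15)
  expect_equal(cal@Veff, pi^1.5 * 0.04, tolerance = 1e-12)

  # degenerate dye fits cannot calibrate
  expect_error(autoFit(N = 2, F1 = 1, tauD1 = 0, S = 5), "tauD1")
  twoComp <- autoFit(N = 2, F1 = 0.8, tauD1 = 25e-6, tauD2 = 1e-3, S = 5,
                     converged = TRUE)
  expect_error(calibrateVolume(twoComp, 427), "single species")
})

test_that("calibration and diffusion-coefficient extraction are exact inverses", {
  dye <- autoFit(N = 2, F1 = 1, tauD1 = 25e-6, S = 5, converged = TRUE)
  cal <- calibrateVolume(dye, dyeD = 400)
  # D -> omega -> D round trip at the calibration point
  expect_equal(diffusionFromTau(cal, 25e-6), 400, tolerance = 1e-12)
  # slow DNA-bound component: omega = 0.2 um, tau = 50 ms -> 0.2 um^2/s
  expect_equal(diffusionFromTau(cal, 0.05), 0.2, tolerance = 1e-12)
  # scaling law: doubling tau halves D
  expect_equal(diffusionFromTau(cal, 2 * 0.05),
               diffusionFromTau(cal, 0.05) / 2, tolerance = 1e-12)
  expect_error(diffusionFromTau(cal, 0), "tauBound")
})

test_that("RCA covers the no-dimer and full-occupancy limits", {
  g <- autoFit(N = 10, converged = TRUE)
  expect_equal(computeRCA(crossFit(Nc = 0, Ng = 10, Nr = 10, converged = TRUE),
                          g), 0)
  expect_equal(computeRCA(crossFit(Nc = 10, Ng = 10, Nr = 10, converged = TRUE),
                          g), 1)
  expect_warning(
    rca <- computeRCA(crossFit(Nc = 10.5, Ng = 10, Nr = 12, converged = TRUE),
                      g), "clipped")
  expect_equal(rca, 1)
  # min-denominator convention
  expect_equal(
    computeRCA(crossFit(Nc = 4, Ng = 10, Nr = 8, converged = TRUE), g,
               denominator = "min"), 0.5)
})

test_that("a half-dimerized mixture recovers RCA near 0.5", {
  mix <- list(
    speciesSpec("dimer", countMean = 30, D = fastD(),
                brightnessGreen = 3e4, brightnessRed = 3e4),
    speciesSpec("free-g", countMean = 30, D = fastD(), brightnessGreen = 3e4),
    speciesSpec("free-r", countMean = 30, D = fastD(), brightnessRed = 3e4))
  rcas <- sapply(1:10, function(s) {
    tr <- simTrace(mix, seed = 400 + s, duration = 2)
    g <- fitSingleComponent(correlateMultitau(tr, "green-auto", blocks = 8))
    r <- fitSingleComponent(correlateMultitau(tr, "red-auto", blocks = 8))
    x <- fitCrosscorrelation(correlateMultitau(tr, "cross", blocks = 8),
                             g, r, fix = c("F1", "tauD1", "tauD2", "S"),
                             initial = crossFit(Nc = 0.3 * g@N, Ng = g@N,
                                                Nr = r@N, F1 = 1,
                                                tauD1 = g@tauD1,
                                                tauD2 = g@tauD1, S = 5))
    suppressWarnings(computeRCA(x, g))
  })
  expect_lt(abs(median(rcas) - 0.5), 0.1)
})

test_that("CPM is intensity per molecule and scales with brightness, not N", {
  g <- autoFit(N = 10, converged = TRUE)
  expect_equal(computeCPM(100e3, g), 10e3)  # 100 kHz / 10 -> 10 kHz/molecule

  # simulation: recovered CPM matches the generating brightness
  cpmAt <- function(count, b, seed) {
    sp <- speciesSpec("m", countMean = count, D = fastD(),
                      brightnessGreen = b)
    tr <- simTrace(sp, seed = seed, duration = 3)
    f <- fitSingleComponent(correlateMultitau(tr, "green-auto", blocks = 8))
    computeCPM(tr, f)
  }
  cpm5 <- median(sapply(1:3, function(s) cpmAt(5 * 24, 5e3, 500 + s)))
  expect_lt(abs(cpm5 - 5e3) / 5e3, 0.2)

  # linear in brightness, invariant to concentration (N in {5, 20} eq.)
  cpmBright <- cpmAt(5 * 24, 1e4, 510)
  expect_lt(abs(cpmBright / cpm5 - 2), 0.35)
  cpmDense <- cpmAt(20 * 24, 5e3, 520)
  expect_lt(abs(cpmDense - cpm5) / cpm5, 0.25)
})

test_that("RCA is invariant to a global brightness rescaling", {
  mk <- function(b, seed) {
    tr <- simTrace(speciesSpec("dimer", countMean = 60, D = fastD(),
                               brightnessGreen = b, brightnessRed = b),
                   seed = seed, duration = 2)
    g <- fitSingleComponent(correlateMultitau(tr, "green-auto", blocks = 8))
    r <- fitSingleComponent(correlateMultitau(tr, "red-auto", blocks = 8))
    x <- fitCrosscorrelation(correlateMultitau(tr, "cross", blocks = 8),
                             g, r, fix = c("F1", "tauD1", "tauD2", "S"),
                             initial = crossFit(Nc = 0.5 * g@N, Ng = g@N,
                                                Nr = r@N, F1 = 1,
                                                tauD1 = g@tauD1,
                                                tauD2 = g@tauD1, S = 5))
    suppressWarnings(computeRCA(x, g))
  }
  expect_lt(abs(mk(1.5e4, 530) - mk(3e4, 530)), 0.15)
})

test_that("bound fraction converts the fast fraction to a percentage", {
  f <- autoFit(N = 10, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5,
               converged = TRUE)
  expect_equal(boundFraction(f), 30)
  single <- autoFit(N = 10, F1 = 1, converged = TRUE)
  expect_error(boundFraction(single), "single-component")

  # recovery from noisy two-component curves with 40% slow species
  truth <- autoFit(N = 10, Ft = 0.1, tauT = 5e-6, F1 = 0.6, tauD1 = 7e-4,
                   tauD2 = 0.05, S = 5)
  x <- crossFit(Nc = 3, F1 = 0.6, tauD1 = 7e-4, tauD2 = 0.05, S = 5)
  bfs <- sapply(1:10, function(s) {
    cur <- generateModelCurves(truth, truth, x, logLagGrid(1e-6, 1, 16),
                               noiseSd = 0.02, seed = 3000 + s)
    fit <- fitAutocorrelation(cur$greenAuto, fix = c("tauD1", "S"),
                              initial = .defaultNoisyInit(tauD1 = 7e-4))
    boundFraction(fit)
  })
  expect_lt(abs(median(bfs) - 40), 8)
})

test_that("group comparison reproduces the pooled-variance t-test", {
  same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # hand-computed: means 2 and 5, pooled var 1, se = sqrt(2/3), df = 4
  cmp <- compareGroups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$t, -3.674235, tolerance = 1e-6)
  expect_equal(cmp$p, 0.02131164, tolerance = 1e-6)
  expect_equal(cmp$df, 4)

  # degenerate zero-variance case
  flat <- compareGroups(c(2, 2), c(2, 2))
  expect_equal(flat$p, 1)

  # power at a 2-SD effect, n = 10 per group
  set.seed(99)
  hits <- mean(replicate(100, {
    compareGroups(rnorm(10, 0), rnorm(10, 2))$p < 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("measurement summaries assemble the per-cell statistics", {
  cal <- calibrateVolume(autoFit(N = 2, F1 = 1, tauD1 = 25e-6, S = 5,
                                 converged = TRUE), 400)
  g <- autoFit(N = 10, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5,
               converged = TRUE)
  r <- autoFit(N = 9, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5,
               converged = TRUE)
  x <- crossFit(Nc = 5, Ng = 10, Nr = 9, converged = TRUE)
  ms <- measurementSummary(g, r, x, intensity = 80e3, cal = cal)
  expect_equal(ms@rca, 0.5)
  expect_equal(ms@cpm, 8e3)
  expect_equal(ms@dBound, 0.2)
  expect_equal(ms@boundFraction, 30)
})
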