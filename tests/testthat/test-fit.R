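# Model fitting: exact recovery, noisy recovery, the fixed-tauD1 convention,
# degeneracy handling and cross-correlation amplitude extraction.

test_that("noiseless autocorrelation curves are recovered to solver tolerance", {
  grid <- logLagGrid(1e-6, 1, 16)
  truth <- autoFit(N = 5, Ft = 0.2, tauT = 5e-6, F1 = 0.6, tauD1 = 7e-4,
                   tauD2 = 0.05, S = 5)
  crv <- correlationCurve("green-auto", grid, evalAutocorrModel(truth, grid))
  fit <- fitAutocorrelation(
    crv, initial = autoFit(N = 2, Ft = 0.1, tauT = 2e-6, F1 = 0.4,
                           tauD1 = 3e-4, tauD2 = 0.01, S = 5), fix = "S")
  expect_true(fit@converged)
  free <- c("N", "Ft", "tauT", "F1", "tauD1", "tauD2")
  expect_true(all(abs(coef(fit)[free] - coef(truth)[free]) /
                  coef(truth)[free] < 1e-6))
})

test_that("noiseless cross-correlation curves are recovered to solver tolerance", {
  grid <- logLagGrid(1e-6, 1, 16)
  truth <- crossFit(Nc = 4, Ng = 10, Nr = 8, F1 = 0.7, tauD1 = 7e-4,
                    tauD2 = 0.05, S = 5)
  crv <- correlationCurve("cross", grid, evalCrosscorrModel(truth, tau = grid))
  gf <- autoFit(N = 10, converged = TRUE)
  rf <- autoFit(N = 8, converged = TRUE)
  fit <- fitCrosscorrelation(
    crv, gf, rf, fix = "S",
    initial = crossFit(Nc = 1, Ng = 10, Nr = 8, F1 = 0.4, tauD1 = 3e-4,
                       tauD2 = 0.02, S = 5))
  expect_true(fit@converged)
  truthVec <- c(Nc = 4, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05)
  expect_true(all(abs(coef(fit)[names(truthVec)] - truthVec) /
                  truthVec < 1e-6))
})

test_that("free parameters are recovered from 1% noise within 10% (median)", {
  grid <- logLagGrid(1e-6, 1, 16)
  truth <- autoFit(N = 10, Ft = 0.15, tauT = 5e-6, F1 = 0.7, tauD1 = 7e-4,
                   tauD2 = 0.05, S = 5)
  x <- crossFit(Nc = 3, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5)
  free <- c("N", "Ft", "tauT", "F1", "tauD1", "tauD2")
  errs <- sapply(1:20, function(s) {
    cur <- generateModelCurves(truth, truth, x, grid, noiseSd = 0.01,
                               seed = 1000 + s)
    fit <- fitAutocorrelation(cur$greenAuto, fix = "S",
                              initial = .defaultNoisyInit())
    abs(coef(fit)[free] - coef(truth)[free]) / coef(truth)[free]
  })
  expect_true(all(apply(errs, 1, median) < 0.10))
})

test_that("fixing tauD1 sharpens the slow-component estimate", {
  grid <- logLagGrid(1e-6, 1, 16)
  truth <- autoFit(N = 10, Ft = 0.15, tauT = 5e-6, F1 = 0.7, tauD1 = 7e-4,
                   tauD2 = 0.05, S = 5)
  x <- crossFit(Nc = 3, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5)
  tauD2Fixed <- tauD2Free <- numeric(10)
  for (s in 1:10) {
    cur <- generateModelCurves(truth, truth, x, grid, noiseSd = 0.03,
                               seed = 2000 + s)
    fFix <- fitAutocorrelation(cur$greenAuto, fix = c("tauD1", "S"),
                               initial = .defaultNoisyInit(tauD1 = 7e-4))
    fFree <- fitAutocorrelation(cur$greenAuto, fix = "S",
                                initial = .defaultNoisyInit())
    tauD2Fixed[s] <- fFix@tauD2
    tauD2Free[s] <- fFree@tauD2
  }
  # fixing the globally determined fast component quantifies the DNA-bound
  # component more precisely
  expect_lt(sd(tauD2Fixed), sd(tauD2Free))
  expect_lt(abs(median(tauD2Fixed) - 0.05) / 0.05, 0.15)
})

test_that("fitted amplitude tracks the generating molecule number monotonically", {
  grid <- logLagGrid(1e-6, 1, 16)
  fitted <- sapply(c(2, 5, 10, 50), function(n) {
    truth <- autoFit(N = n, Ft = 0, F1 = 1, tauD1 = 7e-4, S = 5)
    crv <- correlationCurve("green-auto", grid, evalAutocorrModel(truth, grid))
    fitAutocorrelation(crv, fix = c("Ft", "tauT", "F1", "tauD2", "S"),
                       initial = autoFit(N = 3, F1 = 1, tauD1 = 4e-4,
                                         tauD2 = 4e-4, S = 5))@N
  })
  expect_true(all(diff(fitted) > 0))  # larger N, smaller amplitude 1/N
})

test_that("single-component data fitted with two components is flagged degenerate", {
  grid <- logLagGrid(1e-6, 1, 16)
  truth <- autoFit(N = 10, Ft = 0, F1 = 1, tauD1 = 7e-4, S = 5)
  crv <- correlationCurve("green-auto", grid, evalAutocorrModel(truth, grid))
  fit <- fitAutocorrelation(crv, fix = c("Ft", "tauT", "S"),
                            initial = autoFit(N = 5, Ft = 0, F1 = 0.6,
                                              tauD1 = 4e-4, tauD2 = 8e-3,
                                              S = 5))
  degenerate <- "degenerate-components" %in% fit@flags ||
    fit@F1 > 0.9 || fit@tauD2 / fit@tauD1 < 1.1
  expect_true(degenerate)
})

test_that("curves without amplitude or with too few lags are rejected", {
  flat <- correlationCurve("green-auto", logLagGrid(1e-6, 1, 12),
                           rep(1, length(logLagGrid(1e-6, 1, 12))))
  expect_error(fitAutocorrelation(flat), "no correlation amplitude")
  short <- correlationCurve("green-auto", (1:5) * 1e-5, rep(1.1, 5))
  expect_error(fitAutocorrelation(short), "at least 10 lags")
})

test_that("independent species give no cross amplitude; pure dimers give full", {
  # negative control: independent green-only and red-only species
  nc <- list(
    speciesSpec("g", countMean = 60, D = fastD(), brightnessGreen = 3e4),
    speciesSpec("r", countMean = 60, D = fastD(), brightnessRed = 3e4))
  tr <- simTrace(nc, seed = 91, duration = 2)
  gFit <- fitSingleComponent(correlateMultitau(tr, "green-auto", blocks = 8))
  rFit <- fitSingleComponent(correlateMultitau(tr, "red-auto", blocks = 8))
  xCrv <- correlateMultitau(tr, "cross", blocks = 8)
  xFit <- fitCrosscorrelation(xCrv, gFit, rFit,
                              fix = c("F1", "tauD1", "tauD2", "S"),
                              initial = crossFit(Nc = 0.1, Ng = gFit@N,
                                                 Nr = rFit@N, F1 = 1,
                                                 tauD1 = gFit@tauD1,
                                                 tauD2 = gFit@tauD1, S = 5))
  seNc <- if (is.finite(xFit@stderr["Nc"])) xFit@stderr["Nc"] else 0
  expect_lt(xFit@Nc, max(3 * seNc, 0.1 * gFit@N))

  # pure dimer population: Nc/Ng near 1 (median over seeds)
  dimer <- speciesSpec("dimer", countMean = 80, D = fastD(),
                       brightnessGreen = 3e4, brightnessRed = 3e4)
  ratios <- sapply(1:5, function(s) {
    trd <- simTrace(dimer, seed = 300 + s, duration = 2)
    g <- fitSingleComponent(correlateMultitau(trd, "green-auto", blocks = 8))
    r <- fitSingleComponent(correlateMultitau(trd, "red-auto", blocks = 8))
    x <- fitCrosscorrelation(correlateMultitau(trd, "cross", blocks = 8),
                             g, r, fix = c("F1", "tauD1", "tauD2", "S"),
                             initial = crossFit(Nc = 0.5 * g@N, Ng = g@N,
                                                Nr = r@N, F1 = 1,
                                                tauD1 = g@tauD1,
                                                tauD2 = g@tauD1, S = 5))
    x@Nc / g@N
  })
  expect_lt(abs(median(ratios) - 1), 0.2)
})

test_that("a flat cross curve returns Nc = 0 with a flag instead of an error", {
  grid <- logLagGrid(1e-6, 1, 12)
  set.seed(4)
  g <- 1 + rnorm(length(grid), sd = 1e-4)  # baseline noise only
  crv <- correlationCurve("cross", grid, g)
  gf <- autoFit(N = 10, converged = TRUE)
  rf <- autoFit(N = 10, converged = TRUE)
  fit <- fitCrosscorrelation(crv, gf, rf,
                             fix = c("F1", "tauD1", "tauD2", "S"),
                             initial = crossFit(Nc = 1, Ng = 10, Nr = 10,
                                                F1 = 1, tauD1 = 7e-4,
                                                tauD2 = 7e-4, S = 5))
  expect_lt(fit@Nc, 0.05)
  expect_true(fit@Nc == 0 || fit@Nc < 3 * fit@stderr["Nc"])
})
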