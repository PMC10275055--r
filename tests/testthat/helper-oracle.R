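# Independent transcriptions of the correlation models, used as oracles for
# the package evaluators, plus small simulation helpers shared across tests.

# Second, independent transcription of the two-component + triplet
# autocorrelation. Scalar arithmetic on purpose; no code shared with the
# package implementation.
oracleAuto <- function(tau, N, Ft, tauT, F1, tauD1, tauD2, S) {
  vapply(tau, function(t) {
    triplet <- 1
    if (Ft > 0) triplet <- 1 + (Ft * exp(-t / tauT)) / (1 - Ft)
    d1 <- (1 + t / tauD1)^(-1) * (1 + t / (S * S * tauD1))^(-0.5)
    d2 <- (1 + t / tauD2)^(-1) * (1 + t / (S * S * tauD2))^(-0.5)
    1 + triplet * (F1 * d1 + (1 - F1) * d2) / N
  }, numeric(1))
}

# Independent transcription of the cross-correlation model.
oracleCross <- function(tau, Nc, Ng, Nr, F1, tauD1, tauD2, S) {
  vapply(tau, function(t) {
    d1 <- (1 + t / tauD1)^(-1) * (1 + t / (S * S * tauD1))^(-0.5)
    d2 <- (1 + t / tauD2)^(-1) * (1 + t / (S * S * tauD2))^(-0.5)
    1 + (Nc / (Ng * Nr)) * (F1 * d1 + (1 - F1) * d2)
  }, numeric(1))
}

# Shared fixture geometry: omega = 0.2 um, z0 = 1 um (S = 5), box 6x6x5 radii.
testVolume <- function() observationVolume(omega = 0.2, z0 = 1.0)

# D giving tauD1 = 700 us in the fixture volume.
fastD <- function() 0.2^2 / (4 * 7e-4)

simTrace <- function(species, seed, duration = 2, binWidth = 2e-5,
                     background = 0) {
  suppressWarnings(simulatePhotonTrace(
    species, testVolume(),
    simulationConfig(boxDimensions = c(1.2, 1.2, 5), timeStep = binWidth,
                     duration = duration, binWidth = binWidth,
                     backgroundGreen = background, backgroundRed = background,
                     seed = seed)))
}

# Expected molecules in the observation volume for a species count in the box.
expectedN <- function(count, volume = testVolume(),
                      box = c(1.2, 1.2, 5)) {
  count * effectiveVolume(volume) / prod(box)
}

# Deliberately off-truth starting point for noisy-curve fits.
.defaultNoisyInit <- function(tauD1 = 3e-4) {
  autoFit(N = 5, Ft = 0.1, tauT = 3e-6, F1 = 0.5, tauD1 = tauD1,
          tauD2 = 20 * tauD1, S = 5)
}

# Single-component fit of a simulated trace's autocorrelation (triplet off,
# structure parameter fixed at the fixture value).
fitSingleComponent <- function(curve) {
  amp <- max(gValues(curve)[1] - 1, 1e-3)
  fitAutocorrelation(
    curve,
    initial = autoFit(N = 1 / amp, F1 = 1, tauD1 = 5e-4, tauD2 = 5e-4, S = 5),
    fix = c("Ft", "tauT", "F1", "tauD2", "S"))
}
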