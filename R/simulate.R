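# Synthetic data generation: Brownian-dynamics photon traces, model
# correlation curves with controlled noise, and dose-response tables.

# Run code with a locally set RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Expected diffusion time through the observation volume
#'
#' \eqn{\tau_D = \omega^2 / (4 D)}: the mean lateral residence time of a
#' molecule with diffusion coefficient \code{D} in a volume of lateral radius
#' \code{omega}.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param volume an \code{\linkS4class{ObservationVolume}}.
#' @return diffusion time, s.
#' @examples
#' diffusionTime(400, observationVolume(0.2, 1.0))  # 25 us
#' @export
diffusionTime <- function(D, volume = observationVolume()) {
  stopifnot(is(volume, "ObservationVolume"), all(D > 0))
  volume@omega^2 / (4 * D)
}

#' Simulate a two-channel photon trace
#'
#' Brownian-dynamics forward model of an FCCS measurement: molecules of each
#' species are placed uniformly in a periodic box and displaced every time
#' step by independent Gaussian steps of standard deviation
#' \eqn{\sqrt{2 D \Delta t}} per coordinate. Detection efficiency at position
#' \eqn{(x,y,z)} is \eqn{\exp(-2(x^2+y^2)/\omega^2 - 2z^2/z_0^2)}; triplet
#' blinking is a two-state telegraph process whose stationary dark fraction
#' and relaxation time match the species' triplet parameters. Photon counts
#' per bin are Poisson with mean equal to the integrated detected intensity
#' plus background. Identical seed gives a bit-identical trace.
#'
#' @param species list of \code{\linkS4class{SpeciesSpec}} (a single spec is
#'   accepted).
#' @param volume an \code{\linkS4class{ObservationVolume}}.
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return a \code{\linkS4class{PhotonTrace}} whose \code{provenance} carries
#'   the full ground truth (species, volume, config).
#' @examples
#' sp <- speciesSpec("monomer", countMean = 40, D = 14.3, brightnessGreen = 3e4)
#' tr <- simulatePhotonTrace(sp, observationVolume(),
#'                           simulationConfig(duration = 0.2, seed = 7))
#' tr
#' @export
simulatePhotonTrace <- function(species, volume = observationVolume(),
                                config = simulationConfig()) {
  if (is(species, "SpeciesSpec")) species <- list(species)
  stopifnot(length(species) >= 1,
            all(vapply(species, is, logical(1), "SpeciesSpec")),
            is(volume, "ObservationVolume"), is(config, "SimulationConfig"))
  lapply(species, validObject)
  validObject(volume)
  validObject(config)

  box <- config@boxDimensions
  if (any(box < 5 * c(volume@omega, volume@omega, volume@z0)))
    stop("boxDimensions: box must be at least 5x (omega, omega, z0) to ",
         "suppress periodic-boundary artifacts")

  hasSignal <- any(vapply(species, function(s)
    s@countMean > 0 && (s@brightnessGreen > 0 || s@brightnessRed > 0),
    logical(1)))
  if (!hasSignal && config@backgroundGreen == 0 && config@backgroundRed == 0)
    warning("no species with positive count and brightness, and no background: ",
            "the trace will be all zeros")

  stepsPerBin <- max(1L, as.integer(round(config@binWidth / config@timeStep)))
  dt <- config@binWidth / stepsPerBin
  nb <- as.integer(floor(config@duration / config@binWidth + 1e-9))

  slowestTau <- max(vapply(species, function(s)
    diffusionTime(s@D, volume), numeric(1)))
  if (config@duration < 100 * slowestTau)
    warning(sprintf(
      "duration (%.3g s) < 100x the slowest diffusion time (%.3g s); ",
      config@duration, slowestTau),
      "correlation estimates at long lags will be noisy")

  res <- .withSeed(config@seed,
    .simulateTraceCpp(
      nMol = vapply(species, function(s) as.integer(round(s@countMean)),
                    integer(1)),
      D = vapply(species, function(s) s@D, numeric(1)),
      # brightness slots are apparent (effective-volume averaged) counts per
      # molecule; the peak emission at the volume center is 2*sqrt(2) higher
      # for a 3D Gaussian profile, so that a perfect measurement's FI/N
      # recovers the stated brightness.
      bG = vapply(species, function(s) s@brightnessGreen * 2 * sqrt(2),
                  numeric(1)),
      bR = vapply(species, function(s) s@brightnessRed * 2 * sqrt(2),
                  numeric(1)),
      ft = vapply(species, function(s) s@tripletFraction, numeric(1)),
      tt = vapply(species, function(s) s@tripletTime, numeric(1)),
      box = box, omega = volume@omega, z0 = volume@z0,
      dt = dt, stepsPerBin = stepsPerBin, nBins = nb,
      bgGreen = config@backgroundGreen, bgRed = config@backgroundRed))

  photonTrace(
    binWidth = config@binWidth,
    countsGreen = res$green, countsRed = res$red,
    provenance = list(origin = "simulation", species = species,
                      volume = volume, config = config))
}

#' Generate model correlation curves with controlled noise
#'
#' Evaluates the autocorrelation model (green and red channels) and the
#' cross-correlation model exactly on a lag grid, then perturbs each point
#' with independent Gaussian noise of standard deviation
#' \code{noiseSd * (G(tau) - 1)} -- multiplicative on the fluctuation part, so
#' the G -> 1 tail stays well-behaved. \code{noiseSd = 0} returns the exact
#' model curves.
#'
#' @param autoParamsGreen,autoParamsRed \code{\linkS4class{AutoFit}} parameter
#'   sets for the two autocorrelation channels.
#' @param crossParams a \code{\linkS4class{CrossFit}} parameter set; its
#'   \code{Ng}/\code{Nr} default to the \code{N} of the two auto sets.
#' @param lagGrid lag times, s, strictly increasing.
#' @param noiseSd relative noise level (>= 0).
#' @param seed RNG seed (NA for the current RNG state).
#' @return named list of three \code{\linkS4class{CorrelationCurve}} objects:
#'   \code{greenAuto}, \code{redAuto}, \code{cross}.
#' @examples
#' g <- autoFit(N = 10, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5)
#' x <- crossFit(Nc = 4, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5)
#' curves <- generateModelCurves(g, g, x, logLagGrid(), noiseSd = 0.01, seed = 1)
#' curves$cross
#' @export
generateModelCurves <- function(autoParamsGreen, autoParamsRed, crossParams,
                                lagGrid = logLagGrid(), noiseSd = 0,
                                seed = NA) {
  stopifnot(is(autoParamsGreen, "AutoFit"), is(autoParamsRed, "AutoFit"),
            is(crossParams, "CrossFit"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (any(diff(lagGrid) <= 0) || any(lagGrid <= 0))
    stop("lagGrid must be positive and strictly increasing")
  Ng <- if (is.finite(crossParams@Ng)) crossParams@Ng else autoParamsGreen@N
  Nr <- if (is.finite(crossParams@Nr)) crossParams@Nr else autoParamsRed@N

  gg <- evalAutocorrModel(autoParamsGreen, lagGrid)
  rr <- evalAutocorrModel(autoParamsRed, lagGrid)
  gc <- .gCross(lagGrid, crossParams@Nc, Ng, Nr, crossParams@F1,
                crossParams@tauD1, crossParams@tauD2, crossParams@S)

  .withSeed(seed, {
    perturb <- function(g) {
      if (noiseSd == 0) g
      else g + rnorm(length(g), sd = noiseSd * abs(g - 1))
    }
    list(
      greenAuto = correlationCurve("green-auto", lagGrid, perturb(gg)),
      redAuto = correlationCurve("red-auto", lagGrid, perturb(rr)),
      cross = correlationCurve("cross", lagGrid, perturb(gc)))
  })
}

#' Quasi-logarithmic lag grid
#'
#' A strictly increasing lag grid spanning several decades, mimicking a
#' hardware correlator's output grid; convenient for model-curve generation.
#'
#' @param tauMin,tauMax grid limits, s.
#' @param pointsPerDecade grid density.
#' @return numeric vector of lags, s.
#' @export
logLagGrid <- function(tauMin = 1e-6, tauMax = 1, pointsPerDecade = 16) {
  stopifnot(tauMin > 0, tauMax > tauMin, pointsPerDecade >= 2)
  n <- ceiling(log10(tauMax / tauMin) * pointsPerDecade) + 1
  10^seq(log10(tauMin), log10(tauMax), length.out = n)
}

#' Generate a synthetic dose-response table
#'
#' Draws replicate responses around the four-parameter logistic
#' \eqn{y(c) = bottom + (top - bottom) / (1 + (c/IC_{50})^{-h})}
#' (the form fitted by \code{\link{fitDoseResponse}}), with Gaussian noise of
#' absolute standard deviation \code{noiseSd} on the response scale. Ground
#' truth is attached as attribute \code{"truth"}.
#'
#' @param ic50 midpoint concentration (> 0), nM by convention.
#' @param hillSlope Hill slope; negative for a response that decreases with
#'   dose.
#' @param top,bottom response plateaus at zero and saturating dose.
#' @param concentrations dose levels (> 0), same units as \code{ic50}.
#' @param replicates replicates per concentration (>= 1).
#' @param noiseSd Gaussian noise SD on the response scale (>= 0).
#' @param seed RNG seed (NA for current RNG state).
#' @return data.frame with columns \code{concentration_nM}, \code{response},
#'   \code{replicate_id}.
#' @examples
#' tab <- generateDoseResponseTable(1250, -0.66, top = 0.45, bottom = 0.10,
#'                                  seed = 1)
#' head(tab)
#' @export
generateDoseResponseTable <- function(ic50, hillSlope, top, bottom,
                                      concentrations = 10^seq(1, log10(3e4),
                                                              length.out = 8),
                                      replicates = 3, noiseSd = 0.02,
                                      seed = NA) {
  stopifnot(ic50 > 0, all(concentrations > 0), replicates >= 1)
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  mu <- .logistic4(concentrations, ic50, hillSlope, top, bottom)
  tab <- data.frame(
    concentration_nM = rep(concentrations, each = replicates),
    response = rep(mu, each = replicates),
    replicate_id = rep(seq_len(replicates), times = length(concentrations)))
  if (noiseSd > 0)
    tab$response <- .withSeed(seed,
      tab$response + rnorm(nrow(tab), sd = noiseSd))
  attr(tab, "truth") <- list(ic50 = ic50, hillSlope = hillSlope,
                             top = top, bottom = bottom, noiseSd = noiseSd)
  tab
}
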