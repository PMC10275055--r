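#' @import methods
#' @importFrom stats rnorm rpois sd median setNames coef optimize
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib fccs, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

VALID_PAIRS <- c("green-auto", "red-auto", "cross")

#' Diffusing fluorescent species
#'
#' Ground-truth description of one molecular species for the Brownian-dynamics
#' photon simulator: how many molecules live in the simulation box, how fast
#' they diffuse, how bright they are in each detection channel, and their
#' triplet (dark-state) photophysics. A dual-labeled complex (e.g. a
#' heterodimer of a GFP fusion and a Tomato fusion) is a single species with
#' positive brightness in both channels; a chromatin-bound species is
#' represented by a small positive diffusion coefficient, never zero.
#'
#' @slot label character identifier.
#' @slot countMean expected number of molecules in the simulation box.
#' @slot D diffusion coefficient, um^2/s (> 0).
#' @slot brightnessGreen,brightnessRed apparent molecular brightness: detected
#'   photons/s per molecule averaged over the effective observation volume,
#'   i.e. the counts-per-molecule an ideal measurement recovers (>= 0). For a
#'   3D Gaussian profile the emission rate at the volume center is
#'   \eqn{2\sqrt{2}} times this value.
#' @slot tripletFraction stationary dark-state fraction, in [0, 1).
#' @slot tripletTime triplet relaxation time, s (> 0).
#' @export
setClass("SpeciesSpec",
  representation(
    label = "character",
    countMean = "numeric",
    D = "numeric",
    brightnessGreen = "numeric",
    brightnessRed = "numeric",
    tripletFraction = "numeric",
    tripletTime = "numeric"
  )
)

setValidity("SpeciesSpec", function(object) {
  msg <- character()
  if (length(object@countMean) != 1 || is.na(object@countMean) ||
      object@countMean < 0)
    msg <- c(msg, "countMean must be a single non-negative number")
  if (length(object@D) != 1 || is.na(object@D) || object@D <= 0)
    msg <- c(msg, "D must be > 0 (use a small positive D for a bound species)")
  if (object@brightnessGreen < 0 || object@brightnessRed < 0)
    msg <- c(msg, "brightness values must be >= 0")
  if (object@tripletFraction < 0 || object@tripletFraction >= 1)
    msg <- c(msg, "tripletFraction must be in [0, 1)")
  if (object@tripletTime <= 0)
    msg <- c(msg, "tripletTime must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param label,countMean,D,brightnessGreen,brightnessRed,tripletFraction,tripletTime
#'   see the corresponding slots.
#' @return A \code{SpeciesSpec} object.
#' @rdname SpeciesSpec-class
#' @examples
#' speciesSpec("dimer", countMean = 50, D = 14.3,
#'             brightnessGreen = 3e4, brightnessRed = 3e4)
#' @export
speciesSpec <- function(label, countMean, D,
                        brightnessGreen = 0, brightnessRed = 0,
                        tripletFraction = 0, tripletTime = 5e-6) {
  new("SpeciesSpec", label = label, countMean = countMean, D = D,
      brightnessGreen = brightnessGreen, brightnessRed = brightnessRed,
      tripletFraction = tripletFraction, tripletTime = tripletTime)
}

#' 3D Gaussian confocal observation volume
#'
#' The detection efficiency is modeled as
#' \eqn{w(x,y,z) = \exp(-2(x^2+y^2)/\omega^2 - 2 z^2/z_0^2)} with lateral
#' 1/e^2 radius \code{omega} and axial radius \code{z0}. The structure
#' parameter is \eqn{S = z_0/\omega} and the effective volume
#' \eqn{V_{eff} = \pi^{3/2} \omega^2 z_0}.
#'
#' @slot omega lateral 1/e^2 radius, um.
#' @slot z0 axial 1/e^2 radius, um.
#' @export
setClass("ObservationVolume",
  representation(omega = "numeric", z0 = "numeric")
)

setValidity("ObservationVolume", function(object) {
  msg <- character()
  if (object@omega <= 0) msg <- c(msg, "omega must be > 0")
  if (object@z0 <= object@omega)
    msg <- c(msg, "z0 must exceed omega (structure parameter S = z0/omega > 1)")
  if (length(msg)) msg else TRUE
})

#' @param omega,z0 radii in um.
#' @return An \code{ObservationVolume}.
#' @rdname ObservationVolume-class
#' @export
observationVolume <- function(omega = 0.2, z0 = 1.0) {
  new("ObservationVolume", omega = omega, z0 = z0)
}

#' Simulation configuration
#'
#' Box geometry (periodic boundaries), integration time step, total duration,
#' photon binning and uncorrelated background count rates for the
#' Brownian-dynamics simulator.
#'
#' @slot boxDimensions box edge lengths (x, y, z), um.
#' @slot timeStep Brownian integration step, s.
#' @slot duration total simulated time, s.
#' @slot binWidth photon binning time, s (>= timeStep).
#' @slot backgroundGreen,backgroundRed background count rates, photons/s.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    boxDimensions = "numeric",
    timeStep = "numeric",
    duration = "numeric",
    binWidth = "numeric",
    backgroundGreen = "numeric",
    backgroundRed = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@boxDimensions) != 3 || any(object@boxDimensions <= 0))
    msg <- c(msg, "boxDimensions must be 3 positive edge lengths")
  if (object@timeStep <= 0) msg <- c(msg, "timeStep must be > 0")
  if (object@binWidth < object@timeStep)
    msg <- c(msg, "binWidth must be >= timeStep")
  if (object@duration < object@binWidth)
    msg <- c(msg, "duration must cover at least one bin (duration >= binWidth)")
  if (object@backgroundGreen < 0 || object@backgroundRed < 0)
    msg <- c(msg, "background rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param boxDimensions,timeStep,duration,binWidth,backgroundGreen,backgroundRed,seed
#'   see the corresponding slots.
#' @return A \code{SimulationConfig}.
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(boxDimensions = c(1.2, 1.2, 5.0),
                             timeStep = 1e-5, duration = 10,
                             binWidth = timeStep,
                             backgroundGreen = 0, backgroundRed = 0,
                             seed = 1L) {
  new("SimulationConfig", boxDimensions = as.numeric(boxDimensions),
      timeStep = timeStep, duration = duration, binWidth = binWidth,
      backgroundGreen = backgroundGreen, backgroundRed = backgroundRed,
      seed = as.integer(seed))
}

#' Two-channel binned photon trace
#'
#' Photon counts per time bin in the green and red detection channels, the raw
#' input to correlation analysis. The average count rate of a channel is the
#' fluorescence intensity FI used for molecular brightness (CPM).
#'
#' @slot binWidth bin width, s.
#' @slot countsGreen,countsRed non-negative integer counts per bin (equal length).
#' @slot provenance list carrying simulation ground truth or file origin.
#' @export
setClass("PhotonTrace",
  representation(
    binWidth = "numeric",
    countsGreen = "integer",
    countsRed = "integer",
    provenance = "list"
  )
)

setValidity("PhotonTrace", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (length(object@countsGreen) != length(object@countsRed))
    msg <- c(msg, "countsGreen and countsRed must have equal length")
  if (any(object@countsGreen < 0, na.rm = TRUE) ||
      any(object@countsRed < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param binWidth,countsGreen,countsRed,provenance see the corresponding slots.
#' @return A \code{PhotonTrace}.
#' @rdname PhotonTrace-class
#' @export
photonTrace <- function(binWidth, countsGreen, countsRed,
                        provenance = list()) {
  new("PhotonTrace", binWidth = binWidth,
      countsGreen = as.integer(countsGreen),
      countsRed = as.integer(countsRed),
      provenance = provenance)
}

#' Correlation curve for one channel pair
#'
#' A normalized correlation function \eqn{G(\tau)} on a grid of lag times,
#' with the no-correlation baseline at 1. \code{sdValues} holds the per-lag
#' standard deviation across repeat measurements when available (used as fit
#' weights); otherwise \code{NA}.
#'
#' @slot pair one of \code{"green-auto"}, \code{"red-auto"}, \code{"cross"}.
#' @slot lags lag times, s, strictly increasing.
#' @slot gValues correlation values, dimensionless.
#' @slot sdValues per-lag SD across repeats (or NA).
#' @slot meanIntensityA,meanIntensityB mean count rates of the two correlated
#'   channels, photons/s (NA for model-generated curves).
#' @export
setClass("CorrelationCurve",
  representation(
    pair = "character",
    lags = "numeric",
    gValues = "numeric",
    sdValues = "numeric",
    meanIntensityA = "numeric",
    meanIntensityB = "numeric"
  )
)

setValidity("CorrelationCurve", function(object) {
  msg <- character()
  if (!(object@pair %in% VALID_PAIRS))
    msg <- c(msg, sprintf("pair must be one of: %s",
                          paste(VALID_PAIRS, collapse = ", ")))
  if (length(object@lags) != length(object@gValues))
    msg <- c(msg, "lags and gValues must have equal length")
  if (length(object@lags) > 1 && any(diff(object@lags) <= 0))
    msg <- c(msg, "lags must be strictly increasing")
  if (any(!is.finite(object@gValues)))
    msg <- c(msg, "gValues must all be finite")
  if (length(msg)) msg else TRUE
})

#' @param pair,lags,gValues,sdValues,meanIntensityA,meanIntensityB see slots.
#' @return A \code{CorrelationCurve}.
#' @rdname CorrelationCurve-class
#' @export
correlationCurve <- function(pair, lags, gValues,
                             sdValues = rep(NA_real_, length(lags)),
                             meanIntensityA = NA_real_,
                             meanIntensityB = NA_real_) {
  new("CorrelationCurve", pair = pair, lags = as.numeric(lags),
      gValues = as.numeric(gValues), sdValues = as.numeric(sdValues),
      meanIntensityA = meanIntensityA, meanIntensityB = meanIntensityB)
}

.AUTO_PAR_NAMES <- c("N", "Ft", "tauT", "F1", "tauD1", "tauD2", "S")

#' Autocorrelation model fit
#'
#' Parameters of the two-component free-diffusion model with one triplet state
#' fitted to an autocorrelation curve: total molecule number \code{N} in the
#' observation volume, triplet fraction \code{Ft} and relaxation time
#' \code{tauT}, fast-component fraction \code{F1} with diffusion time
#' \code{tauD1}, slow (DNA-bound) diffusion time \code{tauD2}, and structure
#' parameter \code{S}.
#'
#' @slot N mean molecules in the observation volume (> 0).
#' @slot Ft triplet fraction in [0, 1).
#' @slot tauT triplet relaxation time, s.
#' @slot F1 fraction of the fast component in [0, 1].
#' @slot tauD1,tauD2 diffusion times, s, with tauD2 >= tauD1.
#' @slot S structure parameter (> 1).
#' @slot fixed names of parameters held fixed during fitting.
#' @slot stderr named approximate standard errors of the free parameters.
#' @slot residualNorm weighted residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot flags character vector of diagnostic flags (e.g. degenerate components).
#' @export
setClass("AutoFit",
  representation(
    N = "numeric", Ft = "numeric", tauT = "numeric",
    F1 = "numeric", tauD1 = "numeric", tauD2 = "numeric", S = "numeric",
    fixed = "character", stderr = "numeric",
    residualNorm = "numeric", converged = "logical", flags = "character"
  )
)

setValidity("AutoFit", function(object) {
  msg <- character()
  if (object@N <= 0) msg <- c(msg, "N must be > 0")
  if (object@Ft < 0 || object@Ft >= 1) msg <- c(msg, "Ft must be in [0, 1)")
  if (object@F1 < 0 || object@F1 > 1) msg <- c(msg, "F1 must be in [0, 1]")
  if (object@tauD1 <= 0) msg <- c(msg, "tauD1 must be > 0")
  if (object@tauD2 < object@tauD1) msg <- c(msg, "tauD2 must be >= tauD1")
  if (object@tauT <= 0) msg <- c(msg, "tauT must be > 0")
  if (object@S <= 1) msg <- c(msg, "S must be > 1")
  if (!all(object@fixed %in% .AUTO_PAR_NAMES))
    msg <- c(msg, "fixed must name autocorrelation parameters")
  if (length(msg)) msg else TRUE
})

#' @param N,Ft,tauT,F1,tauD1,tauD2,S,fixed,stderr,residualNorm,converged,flags
#'   see the corresponding slots.
#' @return An \code{AutoFit}.
#' @rdname AutoFit-class
#' @examples
#' autoFit(N = 10, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5)
#' @export
autoFit <- function(N, Ft = 0, tauT = 5e-6, F1 = 1,
                    tauD1 = 7e-4, tauD2 = tauD1, S = 5,
                    fixed = character(), stderr = numeric(),
                    residualNorm = NA_real_, converged = NA, flags = character()) {
  new("AutoFit", N = N, Ft = Ft, tauT = tauT, F1 = F1,
      tauD1 = tauD1, tauD2 = tauD2, S = S, fixed = fixed,
      stderr = stderr, residualNorm = residualNorm,
      converged = as.logical(converged), flags = flags)
}

#' Cross-correlation model fit
#'
#' Parameters of the two-component free-diffusion model (no triplet) fitted to
#' a cross-correlation curve. The amplitude is
#' \eqn{G_c(0) - 1 = N_c / (N_g N_r)} with the channel molecule numbers
#' \code{Ng}, \code{Nr} taken from the two autocorrelation fits, so \code{Nc}
#' is the concentration-equivalent number of double-labeled complexes.
#'
#' @slot Nc number of double-labeled (bound) molecules (>= 0).
#' @slot Ng,Nr molecule numbers imported from the green/red autocorrelation fits.
#' @slot F1,tauD1,tauD2,S as in \code{\linkS4class{AutoFit}}.
#' @slot fixed,stderr,residualNorm,converged,flags as in
#'   \code{\linkS4class{AutoFit}}.
#' @export
setClass("CrossFit",
  representation(
    Nc = "numeric", Ng = "numeric", Nr = "numeric",
    F1 = "numeric", tauD1 = "numeric", tauD2 = "numeric", S = "numeric",
    fixed = "character", stderr = "numeric",
    residualNorm = "numeric", converged = "logical", flags = "character"
  )
)

setValidity("CrossFit", function(object) {
  msg <- character()
  if (object@Nc < 0) msg <- c(msg, "Nc must be >= 0")
  if (object@F1 < 0 || object@F1 > 1) msg <- c(msg, "F1 must be in [0, 1]")
  if (object@tauD1 <= 0) msg <- c(msg, "tauD1 must be > 0")
  if (object@tauD2 < object@tauD1) msg <- c(msg, "tauD2 must be >= tauD1")
  if (object@S <= 1) msg <- c(msg, "S must be > 1")
  if (length(msg)) msg else TRUE
})

#' @param Nc,Ng,Nr,F1,tauD1,tauD2,S,fixed,stderr,residualNorm,converged,flags
#'   see the corresponding slots.
#' @return A \code{CrossFit}.
#' @rdname CrossFit-class
#' @export
crossFit <- function(Nc, Ng = NA_real_, Nr = NA_real_, F1 = 1,
                     tauD1 = 7e-4, tauD2 = tauD1, S = 5,
                     fixed = character(), stderr = numeric(),
                     residualNorm = NA_real_, converged = NA,
                     flags = character()) {
  new("CrossFit", Nc = Nc, Ng = Ng, Nr = Nr, F1 = F1,
      tauD1 = tauD1, tauD2 = tauD2, S = S, fixed = fixed, stderr = stderr,
      residualNorm = residualNorm, converged = as.logical(converged),
      flags = flags)
}

#' Observation-volume calibration from a reference dye
#'
#' Result of calibrating the confocal volume with a dye of known diffusion
#' coefficient: the lateral radius follows from
#' \eqn{\omega = \sqrt{4 D \tau_D}} and the axial radius from
#' \eqn{z_0 = S \omega}.
#'
#' @slot omega lateral radius, um.
#' @slot z0 axial radius, um.
#' @slot S structure parameter.
#' @slot dyeLabel reference dye name.
#' @slot dyeD dye diffusion coefficient, um^2/s.
#' @slot tauDCal calibrated diffusion time, s.
#' @slot Veff effective volume, um^3 (\eqn{\pi^{3/2}\omega^2 z_0}).
#' @export
setClass("CalibrationResult",
  representation(
    omega = "numeric", z0 = "numeric", S = "numeric",
    dyeLabel = "character", dyeD = "numeric", tauDCal = "numeric",
    Veff = "numeric"
  )
)

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (abs(object@omega - sqrt(4 * object@dyeD * object@tauDCal)) >
      1e-12 * object@omega)
    msg <- c(msg, "omega must equal sqrt(4 * dyeD * tauDCal)")
  if (abs(object@z0 - object@S * object@omega) > 1e-12 * object@z0)
    msg <- c(msg, "z0 must equal S * omega")
  if (length(msg)) msg else TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' Midpoint (\code{ic50}), Hill slope (negative for a response that decreases
#' with dose), and the zero-dose (\code{top}) and saturating-dose
#' (\code{bottom}) plateaus of a sigmoidal concentration-response curve.
#'
#' @slot ic50 half-maximal inhibitory concentration (same units as the input
#'   concentrations, nM by convention).
#' @slot hillSlope Hill slope (the allosteric factor).
#' @slot top,bottom response plateaus at zero and saturating dose.
#' @slot stderr named approximate standard errors.
#' @slot residualNorm residual sum of squares.
#' @slot converged logical convergence flag.
#' @export
setClass("DoseResponseFit",
  representation(
    ic50 = "numeric", hillSlope = "numeric", top = "numeric",
    bottom = "numeric", stderr = "numeric", residualNorm = "numeric",
    converged = "logical"
  )
)

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (object@ic50 <= 0) msg <- c(msg, "ic50 must be > 0")
  if (isTRUE(object@converged) && object@top == object@bottom)
    msg <- c(msg, "top and bottom must differ for a converged fit")
  if (length(msg)) msg else TRUE
})

#' Per-cell measurement summary
#'
#' The derived statistics for one measured cell: dimerized fraction (RCA),
#' molecular brightness (CPM), diffusion coefficient of the DNA-bound
#' component and its fractional percentage, with per-repeat values and their
#' mean and SD when the measurement was split into repeats.
#'
#' @slot rca relative cross-correlation amplitude, dimensionless.
#' @slot cpm counts per second per molecule, photons/s (reported in kHz at IO).
#' @slot dBound diffusion coefficient of the DNA-bound component, um^2/s.
#' @slot boundFraction fractional percentage of the DNA-bound component.
#' @slot perRepeat data.frame of per-repeat values (possibly 0 rows).
#' @export
setClass("MeasurementSummary",
  representation(
    rca = "numeric", cpm = "numeric", dBound = "numeric",
    boundFraction = "numeric", perRepeat = "data.frame"
  )
)

setValidity("MeasurementSummary", function(object) {
  msg <- character()
  if (!is.na(object@rca) && object@rca < 0) msg <- c(msg, "rca must be >= 0")
  if (!is.na(object@boundFraction) &&
      (object@boundFraction < 0 || object@boundFraction > 100))
    msg <- c(msg, "boundFraction must be a percentage in [0, 100]")
  if (length(msg)) msg else TRUE
})
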