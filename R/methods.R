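# Accessors and show methods.

#' @rdname ObservationVolume-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("structureParameter", function(x) standardGeneric("structureParameter"))

#' @rdname ObservationVolume-class
#' @export
setMethod("structureParameter", "ObservationVolume",
          function(x) x@z0 / x@omega)

#' @rdname ObservationVolume-class
#' @export
setGeneric("effectiveVolume", function(x) standardGeneric("effectiveVolume"))

#' @rdname ObservationVolume-class
#' @export
setMethod("effectiveVolume", "ObservationVolume",
          function(x) pi^1.5 * x@omega^2 * x@z0)

#' @rdname CalibrationResult-class
#' @param x a \code{CalibrationResult}.
#' @export
setMethod("effectiveVolume", "CalibrationResult",
          function(x) x@Veff)

#' Number of bins and duration of a photon trace
#' @param x a \code{PhotonTrace}.
#' @return \code{nBins}: integer bin count; \code{duration}: total time, s.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname nBins
#' @export
setMethod("nBins", "PhotonTrace", function(x) length(x@countsGreen))

#' @rdname nBins
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname nBins
#' @export
setMethod("duration", "PhotonTrace", function(x) length(x@countsGreen) * x@binWidth)

#' Mean count rate of a trace channel
#' @param x a \code{PhotonTrace}.
#' @param channel \code{"green"} or \code{"red"}.
#' @return mean intensity, photons/s.
#' @export
meanIntensity <- function(x, channel = c("green", "red")) {
  stopifnot(is(x, "PhotonTrace"))
  channel <- match.arg(channel)
  counts <- if (channel == "green") x@countsGreen else x@countsRed
  mean(counts) / x@binWidth
}

#' Lag times and correlation values of a curve
#' @param x a \code{CorrelationCurve}.
#' @return \code{lags}: lag times in s; \code{gValues}: G values;
#'   \code{sdValues}: per-lag SD (NA when unavailable).
#' @export
setGeneric("lags", function(x) standardGeneric("lags"))

#' @rdname lags
#' @export
setMethod("lags", "CorrelationCurve", function(x) x@lags)

#' @rdname lags
#' @export
setGeneric("gValues", function(x) standardGeneric("gValues"))

#' @rdname lags
#' @export
setMethod("gValues", "CorrelationCurve", function(x) x@gValues)

#' @rdname lags
#' @export
setGeneric("sdValues", function(x) standardGeneric("sdValues"))

#' @rdname lags
#' @export
setMethod("sdValues", "CorrelationCurve", function(x) x@sdValues)

#' Fitted parameters as a named vector
#' @param object an \code{AutoFit}, \code{CrossFit} or \code{DoseResponseFit}.
#' @param ... ignored.
#' @return named numeric vector of the model parameters.
#' @export
setMethod("coef", "AutoFit", function(object, ...) {
  c(N = object@N, Ft = object@Ft, tauT = object@tauT, F1 = object@F1,
    tauD1 = object@tauD1, tauD2 = object@tauD2, S = object@S)
})

#' @rdname coef-AutoFit-method
#' @export
setMethod("coef", "CrossFit", function(object, ...) {
  c(Nc = object@Nc, Ng = object@Ng, Nr = object@Nr, F1 = object@F1,
    tauD1 = object@tauD1, tauD2 = object@tauD2, S = object@S)
})

#' @rdname coef-AutoFit-method
#' @export
setMethod("coef", "DoseResponseFit", function(object, ...) {
  c(ic50 = object@ic50, hillSlope = object@hillSlope,
    top = object@top, bottom = object@bottom)
})

setMethod("show", "SpeciesSpec", function(object) {
  cat(sprintf(
    "SpeciesSpec '%s': <n>=%.3g, D=%.3g um^2/s, brightness (G,R)=(%.3g, %.3g) cps, triplet %.0f%% @ %.3g us\n",
    object@label, object@countMean, object@D, object@brightnessGreen,
    object@brightnessRed, 100 * object@tripletFraction,
    object@tripletTime * 1e6))
})

setMethod("show", "ObservationVolume", function(object) {
  cat(sprintf(
    "ObservationVolume: omega=%.3g um, z0=%.3g um (S=%.3g, Veff=%.3g um^3)\n",
    object@omega, object@z0, structureParameter(object),
    effectiveVolume(object)))
})

setMethod("show", "PhotonTrace", function(object) {
  cat(sprintf(
    "PhotonTrace: %d bins x %.3g us (%.3g s total); mean rate green %.3g kHz, red %.3g kHz\n",
    nBins(object), object@binWidth * 1e6, duration(object),
    meanIntensity(object, "green") / 1e3, meanIntensity(object, "red") / 1e3))
})

setMethod("show", "CorrelationCurve", function(object) {
  amp <- if (length(object@gValues)) object@gValues[1] - 1 else NA_real_
  cat(sprintf(
    "CorrelationCurve [%s]: %d lags, %.3g us - %.3g s; G(tau_min)-1 = %.4g\n",
    object@pair, length(object@lags),
    if (length(object@lags)) object@lags[1] * 1e6 else NA,
    if (length(object@lags)) max(object@lags) else NA, amp))
})

setMethod("show", "AutoFit", function(object) {
  cat("AutoFit (two-component diffusion + triplet)\n")
  cat(sprintf("  N      = %.4g\n", object@N))
  cat(sprintf("  Ft     = %.4g, tauT = %.4g us\n", object@Ft, object@tauT * 1e6))
  cat(sprintf("  F1     = %.4g, tauD1 = %.4g us, tauD2 = %.4g ms\n",
              object@F1, object@tauD1 * 1e6, object@tauD2 * 1e3))
  cat(sprintf("  S      = %.4g\n", object@S))
  if (length(object@fixed))
    cat("  fixed:", paste(object@fixed, collapse = ", "), "\n")
  cat(sprintf("  converged: %s; residual norm %.4g\n",
              object@converged, object@residualNorm))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CrossFit", function(object) {
  cat("CrossFit (two-component diffusion)\n")
  cat(sprintf("  Nc = %.4g (Ng = %.4g, Nr = %.4g)\n",
              object@Nc, object@Ng, object@Nr))
  cat(sprintf("  F1 = %.4g, tauD1 = %.4g us, tauD2 = %.4g ms, S = %.4g\n",
              object@F1, object@tauD1 * 1e6, object@tauD2 * 1e3, object@S))
  cat(sprintf("  converged: %s\n", object@converged))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult [%s, D=%.4g um^2/s]: omega=%.4g um, z0=%.4g um, S=%.4g, Veff=%.4g um^3\n",
    object@dyeLabel, object@dyeD, object@omega, object@z0, object@S,
    object@Veff))
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf(
    "DoseResponseFit: IC50 = %.4g, Hill slope = %.3g, top = %.4g, bottom = %.4g (converged: %s)\n",
    object@ic50, object@hillSlope, object@top, object@bottom,
    object@converged))
})

setMethod("show", "MeasurementSummary", function(object) {
  cat(sprintf(
    "MeasurementSummary: RCA = %.3g, CPM = %.3g kHz, D_bound = %.3g um^2/s, bound fraction = %.3g%%\n",
    object@rca, object@cpm / 1e3, object@dBound, object@boundFraction))
  if (nrow(object@perRepeat))
    cat(sprintf("  (%d repeats)\n", nrow(object@perRepeat)))
})
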