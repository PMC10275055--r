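# Derived FCCS statistics: volume calibration, DNA-bound diffusion
# coefficient, relative cross-correlation amplitude (RCA), molecular
# brightness (CPM), bound fraction, and group comparison.

#' Calibrate the observation volume from a reference dye
#'
#' A dye of known diffusion coefficient fixes the volume geometry: the lateral
#' radius is \eqn{\omega = \sqrt{4 D \tau_D}} from the fitted single-component
#' diffusion time, and the axial radius is \eqn{z_0 = S\,\omega} from the
#' fitted structure parameter. Standard reference dyes are ATTO488
#' (D = 400 um^2/s, green channel) and Rhodamine B (D = 427 um^2/s, red
#' channel).
#'
#' @param dyeFit an \code{\linkS4class{AutoFit}} of the calibration
#'   measurement; must be a single-component fit (F1 fixed at 1).
#' @param dyeD the dye's known diffusion coefficient, um^2/s.
#' @param dyeLabel dye name for bookkeeping.
#' @return a \code{\linkS4class{CalibrationResult}} with \code{omega},
#'   \code{z0}, \code{S}, and the effective volume
#'   \eqn{V_{eff} = \pi^{3/2}\omega^2 z_0} attached.
#' @examples
#' dye <- autoFit(N = 3, F1 = 1, tauD1 = 25e-6, S = 5,
#'                fixed = "F1", converged = TRUE)
#' calibrateVolume(dye, dyeD = 400, dyeLabel = "ATTO488")  # omega = 0.2 um
#' @export
calibrateVolume <- function(dyeFit, dyeD, dyeLabel = "dye") {
  stopifnot(is(dyeFit, "AutoFit"))
  if (dyeD <= 0) stop("dyeD must be > 0")
  if (isFALSE(dyeFit@converged)) stop("dye fit did not converge")
  singleComponent <- dyeFit@F1 == 1 ||
    ("F1" %in% dyeFit@fixed && dyeFit@F1 == 1)
  if (!singleComponent)
    stop("calibration requires single species (fit with F1 fixed at 1)")
  if (dyeFit@tauD1 <= 0) stop("invalid fit: tauD1 must be > 0")
  omega <- sqrt(4 * dyeD * dyeFit@tauD1)
  z0 <- dyeFit@S * omega
  new("CalibrationResult", omega = omega, z0 = z0, S = dyeFit@S,
      dyeLabel = dyeLabel, dyeD = dyeD, tauDCal = dyeFit@tauD1,
      Veff = pi^1.5 * omega^2 * z0)
}

#' Diffusion coefficient from a fitted diffusion time
#'
#' Inverts the calibration relation: \eqn{D = \omega^2 / (4 \tau)}. Applied to
#' the fitted slow diffusion time \code{tauD2} this gives the diffusion
#' coefficient of the DNA-bound component.
#'
#' @param cal a \code{\linkS4class{CalibrationResult}}.
#' @param tauBound diffusion time, s (> 0); typically \code{tauD2} of a
#'   two-component fit.
#' @return diffusion coefficient, um^2/s.
#' @export
diffusionFromTau <- function(cal, tauBound) {
  stopifnot(is(cal, "CalibrationResult"))
  if (any(tauBound <= 0)) stop("tauBound must be > 0")
  cal@omega^2 / (4 * tauBound)
}

#' Relative cross-correlation amplitude (RCA)
#'
#' The fraction of green-labeled molecules bound in double-labeled complexes:
#' \eqn{RCA = N_c / N_g}, the ratio of the number of complexes from the
#' cross-correlation fit to the total (free plus bound) number of
#' green-labeled molecules from the green autocorrelation fit. By the
#' convention of the eGFP/Tomato dimerization assay the denominator is the
#' green channel; \code{denominator = "min"} offers the conservative
#' min(Ng, Nr) alternative for general use. Values marginally above 1 (fit
#' noise) are clipped to 1 with a warning.
#'
#' @param cross a \code{\linkS4class{CrossFit}}.
#' @param green the green-channel \code{\linkS4class{AutoFit}}.
#' @param denominator \code{"green"} (default) or \code{"min"}.
#' @return RCA, dimensionless in [0, 1].
#' @export
computeRCA <- function(cross, green, denominator = c("green", "min")) {
  stopifnot(is(cross, "CrossFit"), is(green, "AutoFit"))
  denominator <- match.arg(denominator)
  if (isFALSE(cross@converged) || isFALSE(green@converged))
    stop("fits must have converged")
  den <- switch(denominator, green = green@N, min = min(cross@Ng, cross@Nr))
  if (!is.finite(den) || den <= 0) stop("denominator molecule number must be > 0")
  rca <- cross@Nc / den
  if (rca > 1) {
    warning(sprintf("RCA = %.3g > 1 clipped to 1 (fit noise)", rca))
    rca <- 1
  }
  rca
}

#' Molecular brightness: counts per second per molecule (CPM)
#'
#' \eqn{CPM = FI / N}: the mean fluorescence count rate divided by the number
#' of molecules in the observation volume from the autocorrelation amplitude.
#' Brightness reports on homodimerization: a homodimer carrying two identical
#' fluorophores is twice as bright as the monomer.
#'
#' @param intensity mean count rate FI, photons/s, or a
#'   \code{\linkS4class{PhotonTrace}} (green channel used).
#' @param fit the channel's \code{\linkS4class{AutoFit}}.
#' @param channel trace channel used when \code{intensity} is a trace.
#' @return CPM in photons/s per molecule (divide by 1e3 for kHz).
#' @export
computeCPM <- function(intensity, fit, channel = c("green", "red")) {
  stopifnot(is(fit, "AutoFit"))
  if (is(intensity, "PhotonTrace"))
    intensity <- meanIntensity(intensity, match.arg(channel))
  if (!is.finite(intensity) || intensity < 0)
    stop("intensity must be a non-negative count rate")
  if (fit@N <= 0) stop("fitted N must be > 0")
  intensity / fit@N
}

#' Fractional percentage of the DNA-bound component
#'
#' \eqn{100 (1 - F_1)}: the percentage of molecules in the slow
#' (chromatin-bound) diffusion component of a two-component fit.
#'
#' @param fit a two-component \code{\linkS4class{AutoFit}}.
#' @return percentage in [0, 100].
#' @export
boundFraction <- function(fit) {
  stopifnot(is(fit, "AutoFit"))
  if (isFALSE(fit@converged)) stop("fit did not converge")
  if (fit@F1 == 1)
    stop("single-component fit: no DNA-bound component to report")
  100 * (1 - fit@F1)
}

#' Two-sample comparison by Student's t-test
#'
#' Classic pooled-variance two-sided two-sample t-test for comparing derived
#' statistics (RCA, CPM, D_bound) between treatment groups. The degenerate
#' case of zero variance in both groups with equal means returns t = 0,
#' p = 1.
#'
#' @param valuesA,valuesB numeric vectors (each n >= 2).
#' @return data.frame with the group means, difference of means (A - B),
#'   pooled-variance t statistic, degrees of freedom and two-sided p value.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))
#' @export
compareGroups <- function(valuesA, valuesB) {
  stopifnot(length(valuesA) >= 2, length(valuesB) >= 2)
  out <- data.frame(meanA = mean(valuesA), meanB = mean(valuesB),
                    diff = mean(valuesA) - mean(valuesB),
                    t = NA_real_,
                    df = length(valuesA) + length(valuesB) - 2,
                    p = NA_real_)
  if (sd(valuesA) == 0 && sd(valuesB) == 0) {
    if (mean(valuesA) == mean(valuesB)) {
      out$t <- 0; out$p <- 1
    } else {
      out$t <- sign(out$diff) * Inf; out$p <- 0
    }
    return(out)
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = TRUE,
                      alternative = "two.sided")
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out
}

#' Summarize one measurement into the headline statistics
#'
#' Convenience wrapper combining the derived metrics for one cell: RCA from
#' the cross and green fits, CPM from the trace intensity and green fit,
#' DNA-bound diffusion coefficient from the green fit's slow diffusion time
#' via the calibration, and the bound-component percentage.
#'
#' @param greenFit,redFit,crossFit fitted models for the three curves.
#' @param intensity mean green count rate, photons/s (or a
#'   \code{\linkS4class{PhotonTrace}}).
#' @param cal a \code{\linkS4class{CalibrationResult}}.
#' @param perRepeat optional data.frame of per-repeat values.
#' @return a \code{\linkS4class{MeasurementSummary}}.
#' @export
measurementSummary <- function(greenFit, redFit, crossFit, intensity, cal,
                               perRepeat = data.frame()) {
  rca <- computeRCA(crossFit, greenFit)
  cpm <- computeCPM(intensity, greenFit)
  dB <- diffusionFromTau(cal, greenFit@tauD2)
  bf <- if (greenFit@F1 < 1) boundFraction(greenFit) else NA_real_
  new("MeasurementSummary", rca = rca, cpm = cpm, dBound = dB,
      boundFraction = bf, perRepeat = perRepeat)
}
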