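# Correlation model functions for free 3D diffusion through a Gaussian
# observation volume: two diffusing components plus (for autocorrelation)
# one triplet dark state.

# Single-component 3D diffusion factor (1+t/tD)^-1 (1+t/(S^2 tD))^-1/2.
.diffFactor <- function(tau, tauD, S) {
  1 / ((1 + tau / tauD) * sqrt(1 + tau / (S^2 * tauD)))
}

# Two-component diffusion mixture.
.twoCompFactor <- function(tau, F1, tauD1, tauD2, S) {
  F1 * .diffFactor(tau, tauD1, S) + (1 - F1) * .diffFactor(tau, tauD2, S)
}

# Raw autocorrelation model on numeric parameters; vectorized over tau.
.gAuto <- function(tau, N, Ft, tauT, F1, tauD1, tauD2, S) {
  trip <- if (Ft > 0) 1 + (Ft / (1 - Ft)) * exp(-tau / tauT) else 1
  1 + trip * (1 / N) * .twoCompFactor(tau, F1, tauD1, tauD2, S)
}

# Raw cross-correlation model; no triplet term.
.gCross <- function(tau, Nc, Ng, Nr, F1, tauD1, tauD2, S) {
  1 + (Nc / (Ng * Nr)) * .twoCompFactor(tau, F1, tauD1, tauD2, S)
}

#' Evaluate the autocorrelation model
#'
#' Computes the two-component free-diffusion autocorrelation with one triplet
#' state,
#' \deqn{G(\tau) = 1 + \left[1 + \frac{F_t}{1-F_t} e^{-\tau/\tau_t}\right]
#'   \frac{1}{N}\left[F_1 \left(1+\frac{\tau}{\tau_{D1}}\right)^{-1}
#'   \left(1+\frac{\tau}{S^2\tau_{D1}}\right)^{-1/2} + (1-F_1)
#'   \left(1+\frac{\tau}{\tau_{D2}}\right)^{-1}
#'   \left(1+\frac{\tau}{S^2\tau_{D2}}\right)^{-1/2}\right].}
#' The triplet exponential decays with \eqn{\tau} and the axial de-correlation
#' carries the squared structure parameter, the standard forms for a 3D
#' Gaussian observation volume.
#'
#' @param params an \code{\linkS4class{AutoFit}} holding the model parameters.
#' @param tau lag time(s), s; vectorized.
#' @return numeric vector of G values (>= 1 at tau = 0, -> 1 as tau -> Inf).
#' @examples
#' p <- autoFit(N = 10, F1 = 1, tauD1 = 7e-4, S = 5)
#' evalAutocorrModel(p, 0)      # 1 + 1/N = 1.1
#' evalAutocorrModel(p, c(1e-5, 7e-4, 1))
#' @export
evalAutocorrModel <- function(params, tau) {
  stopifnot(is(params, "AutoFit"))
  validObject(params)
  .gAuto(tau, params@N, params@Ft, params@tauT, params@F1,
         params@tauD1, params@tauD2, params@S)
}

#' Evaluate the cross-correlation model
#'
#' Computes the two-component free-diffusion cross-correlation
#' \deqn{G_c(\tau) = 1 + \frac{N_c}{N_g N_r}\left[F_1 (\ldots) +
#'   (1-F_1)(\ldots)\right]}
#' with the same diffusion factors as \code{\link{evalAutocorrModel}} and no
#' triplet term. The amplitude \eqn{N_c/(N_g N_r)} ties the number of
#' double-labeled complexes \eqn{N_c} to the channel molecule numbers.
#'
#' @param params a \code{\linkS4class{CrossFit}}.
#' @param Ng,Nr molecule numbers from the green/red autocorrelation fits;
#'   defaults to the values stored in \code{params}.
#' @param tau lag time(s), s; vectorized.
#' @return numeric vector of G values.
#' @export
evalCrosscorrModel <- function(params, Ng = params@Ng, Nr = params@Nr, tau) {
  stopifnot(is(params, "CrossFit"))
  validObject(params)
  if (!is.finite(Ng) || !is.finite(Nr) || Ng <= 0 || Nr <= 0)
    stop("Ng and Nr must be positive (take them from the autocorrelation fits)")
  .gCross(tau, params@Nc, Ng, Nr, params@F1,
          params@tauD1, params@tauD2, params@S)
}
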