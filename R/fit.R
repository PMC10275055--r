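# Weighted Levenberg-Marquardt fitting of the correlation models.
#
# Constraints are enforced by reparameterization to an unconstrained scale:
#   N, tauT, tauD1 > 0        : log
#   Ft, F1 in (0, 1)          : logit
#   tauD2 >= tauD1            : tauD2 = tauD1 * (1 + exp(u))
#   S > 1                     : log(S - 1)
# so the optimizer never leaves the physical region and the slow component
# can never cross below the fast one.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Triplet relaxation is a microsecond-scale photophysical process; bounding
# tauT (log-logistic between these limits) keeps the triplet term from
# mimicking the millisecond diffusion decay, a classic exchange degeneracy.
.TAUT_LO <- 1e-7
.TAUT_HI <- 1e-4

.toUnconstrained <- function(name, value, tauD1 = NULL) {
  switch(name,
    N = log(value),
    Nc = value,                        # amplitude enters linearly; clamped later
    Ft = stats::qlogis(.clamp(value, 1e-6, 1 - 1e-6)),
    tauT = stats::qlogis(.clamp(
      (log(value) - log(.TAUT_LO)) / (log(.TAUT_HI) - log(.TAUT_LO)),
      1e-6, 1 - 1e-6)),
    F1 = stats::qlogis(.clamp(value, 1e-6, 1 - 1e-6)),
    tauD1 = log(value),
    tauD2 = log(max(value / tauD1 - 1, 1e-8)),
    S = log(value - 1))
}

.fromUnconstrained <- function(name, value, tauD1 = NULL) {
  switch(name,
    N = exp(value),
    Nc = value,
    Ft = stats::plogis(value),
    tauT = exp(log(.TAUT_LO) +
               (log(.TAUT_HI) - log(.TAUT_LO)) * stats::plogis(value)),
    F1 = stats::plogis(value),
    tauD1 = exp(value),
    tauD2 = tauD1 * (1 + exp(value)),
    S = 1 + exp(value))
}

# d(natural)/d(unconstrained), for delta-method standard errors.
.transformGrad <- function(name, natural, tauD1 = NULL) {
  switch(name,
    N = natural,
    Nc = 1,
    Ft = natural * (1 - natural),
    tauT = {
      p <- (log(natural) - log(.TAUT_LO)) / (log(.TAUT_HI) - log(.TAUT_LO))
      natural * (log(.TAUT_HI) - log(.TAUT_LO)) * p * (1 - p)
    },
    F1 = natural * (1 - natural),
    tauD1 = natural,
    tauD2 = natural - tauD1,
    S = natural - 1)
}

.fitWeights <- function(curve) {
  s <- sdValues(curve)
  if (length(s) == length(lags(curve)) && all(is.finite(s)) && all(s > 0))
    1 / s
  else rep(1, length(lags(curve)))
}

.checkCurveForFit <- function(curve) {
  tau <- lags(curve)
  if (length(tau) < 10)
    stop("need at least 10 lags to fit the correlation model")
  if (log10(max(tau) / min(tau)) < 3)
    warning("lag grid spans fewer than 3 decades; ",
            "diffusion times may be poorly constrained")
  if (all(gValues(curve) <= 1)) stop("no correlation amplitude")
}

# Amplitude/half-decay based initialization; removes manual seeding.
.initAutoFromCurve <- function(curve, S = 5) {
  g <- gValues(curve); tau <- lags(curve)
  amp <- max(g[1] - 1, 1e-3)
  below <- which(g - 1 <= amp / 2)
  tauHalf <- if (length(below)) tau[below[1]] else tau[length(tau)] / 2
  tauHalf <- .clamp(tauHalf, tau[1], tau[length(tau)])
  autoFit(N = 1 / amp, Ft = 0.05, tauT = 5e-6, F1 = 0.7,
          tauD1 = tauHalf / 2, tauD2 = .clamp(tauHalf * 20, tauHalf,
                                              10 * tau[length(tau)]),
          S = S)
}

.runLM <- function(par, residFun) {
  # iteration-limit warnings are redundant: convergence is reported through
  # the info code and the fit's converged flag
  suppressWarnings(minpack.lm::nls.lm(
    par = par, fn = residFun,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, maxfev = 100000, ftol = 1e-15, ptol = 1e-15, gtol = 0)))
}

# info codes 1-3: ftol/ptol satisfied; 6-8: no reduction beyond the requested
# (machine-level) tolerances is possible, i.e. converged as far as the
# arithmetic allows.
.lmConverged <- function(lmFit) lmFit$info %in% c(1:3, 6:8)

# Levenberg-Marquardt is local and the two-component model has flat,
# exchangeable directions (a very slow component mimics a baseline offset), so
# each fit is restarted from a small set of perturbed starting points and the
# lowest weighted residual norm wins.
.runLMMulti <- function(par0List, residFun) {
  best <- NULL
  for (par0 in par0List) {
    fit <- tryCatch(.runLM(par0, residFun), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}

# Perturbed starting points on the unconstrained scale for the diffusion-time
# and fraction parameters.
.multiStarts <- function(par0, freeNames) {
  starts <- list(par0)
  bump <- function(par, nm, delta) {
    if (nm %in% freeNames) par[[nm]] <- par[[nm]] + delta
    par
  }
  starts <- c(starts,
              list(bump(par0, "tauD2", 2.5), bump(par0, "tauD2", -2.5)))
  p <- bump(bump(par0, "tauD1", -1), "tauD2", 1.5)
  starts <- c(starts, list(p))
  if ("F1" %in% freeNames) {
    p <- par0; p[["F1"]] <- 0  # F1 = 0.5 on the logit scale
    starts <- c(starts, list(p))
  }
  unique(starts)
}

# Standard errors on the natural scale from the solver's covariance
# (delta method on the reparameterization).
.naturalStderr <- function(lmFit, freeNames, natural) {
  se <- rep(NA_real_, length(freeNames))
  names(se) <- freeNames
  cv <- tryCatch({
    dof <- max(1, length(lmFit$fvec) - length(freeNames))
    s2 <- sum(lmFit$fvec^2) / dof
    s2 * solve(lmFit$hessian)
  }, error = function(e) NULL)
  if (!is.null(cv)) {
    d <- diag(cv)
    d[d < 0] <- NA_real_
    for (i in seq_along(freeNames)) {
      g <- .transformGrad(freeNames[i], natural[[freeNames[i]]],
                          tauD1 = natural[["tauD1"]])
      se[i] <- abs(g) * sqrt(d[i])
    }
  }
  se
}

#' Fit the autocorrelation model to a curve
#'
#' Weighted least-squares fit of the two-component diffusion model with one
#' triplet state (\code{\link{evalAutocorrModel}}) by Levenberg-Marquardt.
#' Weights are \code{1/sd^2} when the curve carries per-lag standard
#' deviations, unity otherwise. Any subset of parameters can be held fixed at
#' its value in \code{initial} -- the analysis convention for live-cell data
#' is to fix the fast (free-protein) diffusion time, determined globally
#' across measurements, so that the slow DNA-bound component is quantified
#' precisely; the structure parameter is normally fixed from dye calibration.
#'
#' Starting values default to amplitude-based initialization:
#' \code{N} from \code{1/(G(tau_min) - 1)} and diffusion times from the lag of
#' half-amplitude decay. When free, the triplet relaxation time is constrained
#' to the photophysically plausible 0.1-100 us window so the triplet term
#' cannot trade off against the millisecond diffusion decay.
#'
#' @param curve a \code{\linkS4class{CorrelationCurve}} (auto pair).
#' @param initial an \code{\linkS4class{AutoFit}} of starting values, or NULL
#'   for automatic initialization.
#' @param fix character vector of parameter names to hold fixed at their
#'   \code{initial} values (subset of N, Ft, tauT, F1, tauD1, tauD2, S).
#' @return an \code{\linkS4class{AutoFit}}. Non-convergence is reported via
#'   the \code{converged} flag (parameters are still returned); near-equal
#'   fitted diffusion times (within 10 percent) add a
#'   \code{"degenerate-components"} flag.
#' @examples
#' truth <- autoFit(N = 8, F1 = 0.7, tauD1 = 7e-4, tauD2 = 0.05, S = 5)
#' crv <- correlationCurve("green-auto", logLagGrid(),
#'                         evalAutocorrModel(truth, logLagGrid()))
#' fitAutocorrelation(crv, fix = c("Ft", "tauT", "S"),
#'                    initial = autoFit(N = 5, F1 = 0.5, tauD1 = 1e-3,
#'                                      tauD2 = 0.02, S = 5))
#' @export
fitAutocorrelation <- function(curve, initial = NULL, fix = "S") {
  stopifnot(is(curve, "CorrelationCurve"))
  .checkCurveForFit(curve)
  fix <- as.character(fix)
  if (!all(fix %in% .AUTO_PAR_NAMES))
    stop("fix must name autocorrelation parameters: ",
         paste(.AUTO_PAR_NAMES, collapse = ", "))
  if (is.null(initial)) initial <- .initAutoFromCurve(curve)
  validObject(initial)

  tau <- lags(curve); g <- gValues(curve); w <- .fitWeights(curve)
  freeNames <- setdiff(.AUTO_PAR_NAMES, fix)
  if (!length(freeNames)) stop("at least one parameter must be free")
  init <- coef(initial)
  # triplet-free starting point would pin Ft at the logit boundary
  if ("Ft" %in% freeNames && init[["Ft"]] == 0) init[["Ft"]] <- 0.05
  if ("tauD2" %in% freeNames && init[["tauD2"]] <= init[["tauD1"]])
    init[["tauD2"]] <- 2 * init[["tauD1"]]

  natFromPar <- function(par) {
    nat <- as.list(init)
    # tauD1 first: the tauD2 back-transform needs it
    if ("tauD1" %in% freeNames)
      nat$tauD1 <- .fromUnconstrained("tauD1", par[["tauD1"]])
    for (nm in setdiff(freeNames, "tauD1"))
      nat[[nm]] <- .fromUnconstrained(nm, par[[nm]], tauD1 = nat$tauD1)
    if (!("tauD2" %in% freeNames) && nat$tauD2 < nat$tauD1)
      nat$tauD2 <- nat$tauD1
    nat
  }
  par0 <- vapply(freeNames, function(nm)
    .toUnconstrained(nm, init[[nm]], tauD1 = init[["tauD1"]]), numeric(1))
  residFun <- function(par) {
    nat <- natFromPar(setNames(par, freeNames))
    w * (.gAuto(tau, nat$N, nat$Ft, nat$tauT, nat$F1,
                nat$tauD1, nat$tauD2, nat$S) - g)
  }
  lmFit <- .runLMMulti(.multiStarts(par0, freeNames), residFun)
  nat <- natFromPar(setNames(lmFit$par, freeNames))

  flags <- character()
  if (abs(nat$tauD2 / nat$tauD1 - 1) < 0.1 && "tauD2" %in% freeNames)
    flags <- c(flags, "degenerate-components")

  autoFit(N = nat$N, Ft = nat$Ft, tauT = nat$tauT, F1 = nat$F1,
          tauD1 = nat$tauD1, tauD2 = max(nat$tauD2, nat$tauD1), S = nat$S,
          fixed = fix,
          stderr = .naturalStderr(lmFit, freeNames, nat),
          residualNorm = sum(lmFit$fvec^2),
          converged = .lmConverged(lmFit),
          flags = flags)
}

#' Fit the cross-correlation model to a curve
#'
#' Fits the two-component diffusion model (no triplet) to a cross-correlation
#' curve with the channel molecule numbers \code{Ng} and \code{Nr} fixed from
#' the two autocorrelation fits, so the amplitude directly yields the number
#' of double-labeled complexes \code{Nc}. A flat curve (no amplitude) is not
#' an error -- it is the biological negative control -- and returns
#' \code{Nc = 0} with a \code{"flat-curve"} flag.
#'
#' @param curve a \code{\linkS4class{CorrelationCurve}} (cross pair).
#' @param greenFit,redFit converged \code{\linkS4class{AutoFit}} objects for
#'   the two channels.
#' @param initial a \code{\linkS4class{CrossFit}} of starting values, or NULL
#'   to start from the curve amplitude and the green fit's diffusion
#'   parameters.
#' @param fix parameter names (of Nc, F1, tauD1, tauD2, S) to hold fixed.
#' @return a \code{\linkS4class{CrossFit}}.
#' @export
fitCrosscorrelation <- function(curve, greenFit, redFit, initial = NULL,
                                fix = "S") {
  stopifnot(is(curve, "CorrelationCurve"),
            is(greenFit, "AutoFit"), is(redFit, "AutoFit"))
  if (isFALSE(greenFit@converged) || isFALSE(redFit@converged))
    stop("both autocorrelation fits must have converged")
  parNames <- c("Nc", "F1", "tauD1", "tauD2", "S")
  fix <- as.character(fix)
  if (!all(fix %in% parNames))
    stop("fix must name cross-correlation parameters: ",
         paste(parNames, collapse = ", "))
  tau <- lags(curve); g <- gValues(curve); w <- .fitWeights(curve)
  if (length(tau) < 10)
    stop("need at least 10 lags to fit the correlation model")
  Ng <- greenFit@N; Nr <- redFit@N

  amp0 <- max(g[1] - 1, 0)
  if (is.null(initial))
    initial <- crossFit(Nc = max(amp0 * Ng * Nr, 1e-3 * min(Ng, Nr)),
                        Ng = Ng, Nr = Nr,
                        F1 = greenFit@F1, tauD1 = greenFit@tauD1,
                        tauD2 = greenFit@tauD2, S = greenFit@S)
  validObject(initial)
  init <- c(Nc = initial@Nc, F1 = initial@F1, tauD1 = initial@tauD1,
            tauD2 = initial@tauD2, S = initial@S)
  freeNames <- setdiff(parNames, fix)
  if (!length(freeNames)) stop("at least one parameter must be free")
  if ("tauD2" %in% freeNames && init[["tauD2"]] <= init[["tauD1"]])
    init[["tauD2"]] <- 2 * init[["tauD1"]]

  natFromPar <- function(par) {
    nat <- as.list(init)
    if ("tauD1" %in% freeNames)
      nat$tauD1 <- .fromUnconstrained("tauD1", par[["tauD1"]])
    for (nm in setdiff(freeNames, "tauD1"))
      nat[[nm]] <- .fromUnconstrained(nm, par[[nm]], tauD1 = nat$tauD1)
    if (!("tauD2" %in% freeNames) && nat$tauD2 < nat$tauD1)
      nat$tauD2 <- nat$tauD1
    nat
  }
  par0 <- vapply(freeNames, function(nm)
    .toUnconstrained(nm, init[[nm]], tauD1 = init[["tauD1"]]), numeric(1))
  residFun <- function(par) {
    nat <- natFromPar(setNames(par, freeNames))
    w * (.gCross(tau, nat$Nc, Ng, Nr, nat$F1,
                 nat$tauD1, nat$tauD2, nat$S) - g)
  }
  lmFit <- .runLMMulti(.multiStarts(par0, freeNames), residFun)
  nat <- natFromPar(setNames(lmFit$par, freeNames))

  flags <- character()
  ncFit <- nat$Nc
  if (ncFit <= 0) {
    flags <- c(flags, "flat-curve")
    ncFit <- 0
  }
  fitTol <- 0.2
  if (ncFit > min(Ng, Nr) * (1 + fitTol)) {
    warning("fitted Nc exceeds min(Ng, Nr) beyond fit tolerance")
    flags <- c(flags, "Nc-exceeds-channel")
  }
  crossFit(Nc = ncFit, Ng = Ng, Nr = Nr, F1 = nat$F1,
           tauD1 = nat$tauD1, tauD2 = max(nat$tauD2, nat$tauD1), S = nat$S,
           fixed = fix,
           stderr = .naturalStderr(lmFit, freeNames, nat),
           residualNorm = sum(lmFit$fvec^2),
           converged = .lmConverged(lmFit),
           flags = flags)
}
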