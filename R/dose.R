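# Dose-response fitting (four-parameter logistic on log-concentration) and
# the Cheng-Prusoff competitive-inhibition potency shift.

# Four-parameter logistic. With hillSlope < 0 (decreasing response),
# y -> top as c -> 0 and y -> bottom as c -> Inf; y(ic50) = (top+bottom)/2.
.logistic4 <- function(conc, ic50, hillSlope, top, bottom) {
  bottom + (top - bottom) / (1 + (conc / ic50)^(-hillSlope))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{y(c) = bottom + \frac{top - bottom}{1 + (c/IC_{50})^{-h}}}
#' on log-concentration by Levenberg-Marquardt, with \eqn{IC_{50}} fitted on
#' the log scale. The sign convention makes the Hill slope \eqn{h} (the
#' allosteric factor) negative for a response that decreases with dose, as for
#' dimerization (RCA) suppressed by an inhibitor. Zero concentrations are
#' floored at a tenth of the smallest positive dose on the log axis, so
#' zero-dose points inform the \code{top} plateau only.
#'
#' @param table data.frame with columns \code{concentration_nM} (or
#'   \code{concentration}) and \code{response}; replicate rows per
#'   concentration are used as-is.
#' @return a \code{\linkS4class{DoseResponseFit}}. A data set with no
#'   resolvable transition is returned with \code{converged = FALSE}.
#' @examples
#' tab <- generateDoseResponseTable(1250, -0.66, top = 0.45, bottom = 0.10,
#'                                  noiseSd = 0, seed = 1)
#' fitDoseResponse(tab)
#' @export
fitDoseResponse <- function(table) {
  concCol <- intersect(c("concentration_nM", "concentration"), names(table))
  if (!length(concCol) || !"response" %in% names(table))
    stop("table needs columns concentration_nM (or concentration) and response")
  conc <- table[[concCol[1]]]
  resp <- table$response
  keep <- is.finite(conc) & is.finite(resp) & conc >= 0
  conc <- conc[keep]; resp <- resp[keep]
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations")
  minPos <- min(conc[conc > 0])
  conc[conc == 0] <- minPos / 10

  ord <- order(conc)
  top0 <- mean(resp[conc == min(conc)])
  bottom0 <- mean(resp[conc == max(conc)])
  direction <- if (bottom0 <= top0) -1 else 1
  mid <- (top0 + bottom0) / 2
  ic50Idx <- which.min(abs(resp[ord] - mid))
  ic500 <- conc[ord][ic50Idx]

  # par = (log ic50, hill, top, bottom)
  par0 <- c(log(ic500), direction * 0.8, top0, bottom0)
  residFun <- function(par)
    .logistic4(conc, exp(par[1]), par[2], par[3], par[4]) - resp
  lmFit <- .runLM(par0, residFun)
  p <- lmFit$par
  converged <- .lmConverged(lmFit) && is.finite(p[1]) &&
    abs(p[3] - p[4]) > 1e-12

  # only ic50 is reparameterized (log); the others are linear-scale already
  se <- setNames(rep(NA_real_, 4), c("ic50", "hillSlope", "top", "bottom"))
  if (length(lmFit$fvec) > 4 && !is.null(lmFit$hessian)) {
    cv <- tryCatch({
      s2 <- sum(lmFit$fvec^2) / (length(lmFit$fvec) - 4)
      s2 * solve(lmFit$hessian)
    }, error = function(e) NULL)
    if (!is.null(cv)) {
      d <- sqrt(pmax(diag(cv), 0))
      se <- c(ic50 = exp(p[1]) * d[1], hillSlope = d[2],
              top = d[3], bottom = d[4])
    }
  }

  new("DoseResponseFit", ic50 = exp(p[1]), hillSlope = p[2],
      top = p[3], bottom = p[4], stderr = se,
      residualNorm = sum(lmFit$fvec^2), converged = converged)
}

#' Predict the fitted dose-response curve
#'
#' @param fit a \code{\linkS4class{DoseResponseFit}}.
#' @param conc concentrations (> 0), same units as the fitted data.
#' @return predicted responses.
#' @export
predictDoseResponse <- function(fit, conc) {
  stopifnot(is(fit, "DoseResponseFit"))
  .logistic4(conc, fit@ic50, fit@hillSlope, fit@top, fit@bottom)
}

#' Cheng-Prusoff shift of a biochemical IC50 to cellular conditions
#'
#' For a competitive (ATP-site) inhibitor assayed at ATP concentration
#' \code{atpAssay}, the inhibition constant is
#' \eqn{K_i = IC_{50} / (1 + [ATP]_{assay}/K_m)}, and the potency predicted at
#' the cellular ATP level is
#' \eqn{IC_{50}^{cell} = K_i (1 + [ATP]_{cell}/K_m)}. Assays run at
#' \eqn{[ATP] = K_m} give \eqn{K_i = IC_{50}/2}.
#'
#' @param ic50Biochem biochemical IC50, nM.
#' @param atpAssay assay ATP concentration, uM.
#' @param atpCell cellular ATP concentration, uM (typically 1000, i.e. 1 mM).
#' @param kmAtp the kinase's ATP Km, uM.
#' @return list with \code{ki_nM} and \code{ic50Cell_nM}.
#' @examples
#' chengPrusoffShift(20, atpAssay = 2.95, atpCell = 1000, kmAtp = 2.95)
#' @export
chengPrusoffShift <- function(ic50Biochem, atpAssay, atpCell, kmAtp) {
  if (any(c(ic50Biochem, atpAssay, atpCell, kmAtp) <= 0))
    stop("all inputs must be > 0")
  ki <- ic50Biochem / (1 + atpAssay / kmAtp)
  list(ki_nM = ki, ic50Cell_nM = ki * (1 + atpCell / kmAtp))
}
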