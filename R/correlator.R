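# Correlators: a direct (linear-lag) estimator serving as the oracle, and a
# multi-tau estimator with progressive rebinning for the quasi-logarithmic
# grids used in practice.

.pairChannels <- function(trace, pair) {
  a <- switch(pair, "green-auto" = trace@countsGreen,
              "red-auto" = trace@countsRed, "cross" = trace@countsGreen)
  b <- switch(pair, "green-auto" = trace@countsGreen,
              "red-auto" = trace@countsRed, "cross" = trace@countsRed)
  list(a = as.numeric(a), b = as.numeric(b))
}

# Symmetrically normalized correlation estimate at integer lags `ks` (in
# bins): G(k) = <a_t b_{t+k}> / (<a>_seg <b>_seg), means over the
# overlapping segments (local means reduce bias from slow drifts).
.gAtLags <- function(a, b, ks) {
  n <- length(a)
  vapply(ks, function(k) {
    x <- a[seq_len(n - k)]
    y <- b[seq.int(k + 1L, n)]
    mx <- mean(x); my <- mean(y)
    mean(x * y) / (mx * my)
  }, numeric(1))
}

.checkSignal <- function(a, b) {
  if (mean(a) == 0 || mean(b) == 0) stop("channel has no signal")
}

#' Direct correlation estimator
#'
#' Computes the normalized correlation
#' \eqn{G(\tau) = \langle F_a(t) F_b(t+\tau)\rangle /
#' (\langle F_a\rangle \langle F_b\rangle)} at every integer multiple of the
#' bin width up to \code{maxLag}, with symmetric normalization (channel means
#' taken over the overlapping segments at each lag). Lag zero is excluded:
#' in photon counting it is dominated by shot noise. Cost is
#' O(n bins x n lags); this estimator is the reference the multi-tau
#' correlator is checked against.
#'
#' @param trace a \code{\linkS4class{PhotonTrace}}.
#' @param pair \code{"green-auto"}, \code{"red-auto"} or \code{"cross"}.
#' @param maxLag largest lag, s; must be below a tenth of the trace duration.
#' @return a \code{\linkS4class{CorrelationCurve}}.
#' @export
correlateDirect <- function(trace, pair = c("green-auto", "red-auto", "cross"),
                            maxLag = duration(trace) / 20) {
  stopifnot(is(trace, "PhotonTrace"))
  pair <- match.arg(pair)
  if (maxLag >= duration(trace) / 10)
    stop("maxLag must be < trace duration / 10")
  ch <- .pairChannels(trace, pair)
  .checkSignal(ch$a, ch$b)
  kMax <- max(1L, as.integer(floor(maxLag / trace@binWidth)))
  ks <- seq_len(kMax)
  correlationCurve(pair,
                   lags = ks * trace@binWidth,
                   gValues = .gAtLags(ch$a, ch$b, ks),
                   meanIntensityA = mean(ch$a) / trace@binWidth,
                   meanIntensityB = mean(ch$b) / trace@binWidth)
}

# Rebin a numeric series by factor 2 (sum of adjacent pairs).
.rebin2 <- function(v) {
  n2 <- length(v) %/% 2L
  if (n2 < 1L) return(numeric(0))
  v <- v[seq_len(2L * n2)]
  v[seq.int(1L, 2L * n2 - 1L, by = 2L)] + v[seq.int(2L, 2L * n2, by = 2L)]
}

#' Multi-tau correlation estimator
#'
#' Schaetzel-style multi-tau scheme: the first block evaluates
#' \code{channelsPerBlock} linearly spaced lags at the native bin width; after
#' each block both channels are rebinned by a factor of 2 and the next block
#' covers the upper half of the (now doubled) lag range, producing a
#' quasi-logarithmic grid. Each lag uses the same symmetrically normalized
#' estimator as \code{\link{correlateDirect}} on the rebinned series, so the
#' first block agrees with the direct estimator exactly and every later block
#' agrees exactly with the direct estimator applied to the correspondingly
#' rebinned trace.
#'
#' @param trace a \code{\linkS4class{PhotonTrace}}.
#' @param pair channel pair, as in \code{\link{correlateDirect}}.
#' @param channelsPerBlock even number of lag channels per block (default 16).
#' @param blocks number of blocks (>= 1); capped when the rebinned trace
#'   becomes too short.
#' @return a \code{\linkS4class{CorrelationCurve}} on the multi-tau lag grid.
#' @export
correlateMultitau <- function(trace,
                              pair = c("green-auto", "red-auto", "cross"),
                              channelsPerBlock = 16L, blocks = 10L) {
  stopifnot(is(trace, "PhotonTrace"))
  pair <- match.arg(pair)
  m <- as.integer(channelsPerBlock)
  if (m < 2L || m %% 2L != 0L) stop("channelsPerBlock must be even and >= 2")
  if (blocks < 1L) stop("blocks must be >= 1")
  ch <- .pairChannels(trace, pair)
  .checkSignal(ch$a, ch$b)

  a <- ch$a; b <- ch$b
  width <- trace@binWidth
  lagsOut <- numeric(0); gOut <- numeric(0)
  for (blk in seq_len(as.integer(blocks))) {
    ks <- if (blk == 1L) seq_len(m) else seq.int(m %/% 2L + 1L, m)
    if (length(a) <= 2L * max(ks)) break  # too short to rebin further
    lagsOut <- c(lagsOut, ks * width)
    gOut <- c(gOut, .gAtLags(a, b, ks))
    a <- .rebin2(a); b <- .rebin2(b)
    width <- width * 2
  }
  correlationCurve(pair, lags = lagsOut, gValues = gOut,
                   meanIntensityA = mean(ch$a) / trace@binWidth,
                   meanIntensityB = mean(ch$b) / trace@binWidth)
}

#' Correlate repeat segments and average
#'
#' Splits a trace into \code{nSegments} equal segments -- emulating repeated
#' short acquisitions on the same cell -- correlates each, and returns the
#' mean curve with per-lag standard deviation across segments in
#' \code{sdValues}.
#'
#' @param trace a \code{\linkS4class{PhotonTrace}}.
#' @param nSegments number of segments (>= 2, fewer than the bin count).
#' @param pair channel pair.
#' @param method \code{"multitau"} or \code{"direct"}.
#' @param ... passed to the chosen correlator (e.g. \code{maxLag},
#'   \code{channelsPerBlock}, \code{blocks}).
#' @return a \code{\linkS4class{CorrelationCurve}} with \code{sdValues} set.
#' @export
splitAndAverage <- function(trace, nSegments = 10L,
                            pair = c("green-auto", "red-auto", "cross"),
                            method = c("multitau", "direct"), ...) {
  stopifnot(is(trace, "PhotonTrace"))
  pair <- match.arg(pair)
  method <- match.arg(method)
  nSegments <- as.integer(nSegments)
  n <- nBins(trace)
  if (nSegments < 2L) stop("nSegments must be >= 2")
  segLen <- n %/% nSegments
  if (segLen < 4L)
    stop("segments would contain fewer than 4 bins; reduce nSegments")

  corrFun <- if (method == "multitau") correlateMultitau else correlateDirect
  curves <- lapply(seq_len(nSegments), function(i) {
    idx <- seq.int((i - 1L) * segLen + 1L, i * segLen)
    seg <- photonTrace(trace@binWidth, trace@countsGreen[idx],
                       trace@countsRed[idx], provenance = trace@provenance)
    corrFun(seg, pair = pair, ...)
  })
  maxLagUsed <- max(lags(curves[[1]]))
  if (segLen * trace@binWidth < 10 * maxLagUsed)
    warning("segments are shorter than 10x the largest lag; ",
            "per-segment curves will be noisy")
  gMat <- vapply(curves, gValues, numeric(length(lags(curves[[1]]))))
  ch <- .pairChannels(trace, pair)
  correlationCurve(pair, lags = lags(curves[[1]]),
                   gValues = rowMeans(gMat),
                   sdValues = apply(gMat, 1, sd),
                   meanIntensityA = mean(ch$a) / trace@binWidth,
                   meanIntensityB = mean(ch$b) / trace@binWidth)
}
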