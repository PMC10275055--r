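# Plain-text IO: photon traces and correlation curves as CSV, fit results and
# ground truth as JSON. CSV column names carry explicit units.

#' Write / read a photon trace as CSV
#'
#' Columns \code{bin_index}, \code{counts_green}, \code{counts_red}, preceded
#' by comment lines (\code{#}) carrying the bin width and, when the trace came
#' from simulation, the seed.
#'
#' @param trace a \code{\linkS4class{PhotonTrace}}.
#' @param path file path.
#' @return \code{writeTraceCsv}: the path, invisibly. \code{readTraceCsv}: a
#'   \code{\linkS4class{PhotonTrace}}.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "PhotonTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_s=%.17g", trace@binWidth), con)
  cfg <- trace@provenance$config
  if (!is.null(cfg)) writeLines(sprintf("# seed=%d", cfg@seed), con)
  df <- data.frame(bin_index = seq_len(nBins(trace)) - 1L,
                   counts_green = trace@countsGreen,
                   counts_red = trace@countsRed)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  header <- readLines(path, n = 10)
  bwLine <- grep("^#\\s*bin_width_s=", header, value = TRUE)
  if (!length(bwLine)) stop("missing '# bin_width_s=' header in ", path)
  binWidth <- as.numeric(sub("^#\\s*bin_width_s=", "", bwLine[1]))
  df <- read.csv(path, comment.char = "#")
  need <- c("counts_green", "counts_red")
  if (!all(need %in% names(df)))
    stop("trace CSV needs columns: ", paste(need, collapse = ", "))
  photonTrace(binWidth, df$counts_green, df$counts_red,
              provenance = list(origin = path))
}

#' Write / read correlation curves as CSV
#'
#' Long-format CSV with columns \code{lag_s}, \code{g}, \code{sd},
#' \code{pair}; several curves may share one file. Instrument exports with
#' microsecond lags are accepted via \code{lagUnits = "us"}.
#'
#' @param curves a \code{\linkS4class{CorrelationCurve}} or list of them.
#' @param path file path.
#' @param lagUnits \code{"s"} (default) or \code{"us"} for the lag column on
#'   disk.
#' @return \code{writeCurveCsv}: the path, invisibly. \code{readCurveCsv}: a
#'   named list of \code{\linkS4class{CorrelationCurve}} objects (names are
#'   the channel pairs).
#' @export
writeCurveCsv <- function(curves, path, lagUnits = c("s", "us")) {
  lagUnits <- match.arg(lagUnits)
  if (is(curves, "CorrelationCurve")) curves <- list(curves)
  scale <- if (lagUnits == "us") 1e6 else 1
  # full 17-digit precision so written curves read back bit-exact
  num <- function(x) sprintf("%.17g", x)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(lag_s = num(lags(cv) * scale), g = num(gValues(cv)),
               sd = ifelse(is.na(sdValues(cv)), "NA", num(sdValues(cv))),
               pair = cv@pair)))
  if (lagUnits == "us") names(df)[1] <- "lag_us"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCurveCsv
#' @export
readCurveCsv <- function(path, lagUnits = c("s", "us")) {
  lagUnits <- match.arg(lagUnits)
  if (!file.exists(path)) stop("curve file not found: ", path)
  df <- read.csv(path, comment.char = "#")
  lagCol <- intersect(c("lag_s", "lag_us", "lag"), names(df))
  if (!length(lagCol) || !all(c("g", "pair") %in% names(df)))
    stop("curve CSV needs columns lag_s (or lag_us), g, pair")
  lagCol <- lagCol[1]
  scale <- if (lagUnits == "us" || lagCol == "lag_us") 1e-6 else 1
  out <- lapply(split(df, df$pair), function(d) {
    d <- d[order(d[[lagCol]]), ]
    correlationCurve(d$pair[1], d[[lagCol]] * scale, d$g,
                     sdValues = if ("sd" %in% names(d)) d$sd
                                else rep(NA_real_, nrow(d)))
  })
  out
}

.fitToList <- function(fit) {
  if (is(fit, "AutoFit") || is(fit, "CrossFit")) {
    list(model = if (is(fit, "AutoFit"))
           "two-component diffusion + triplet" else "two-component diffusion",
         parameters = as.list(coef(fit)),
         fixed = fit@fixed,
         stderr = as.list(fit@stderr),
         residual_norm = fit@residualNorm,
         converged = fit@converged,
         flags = fit@flags)
  } else if (is(fit, "DoseResponseFit")) {
    list(model = "four-parameter logistic",
         parameters = as.list(coef(fit)),
         stderr = as.list(fit@stderr),
         residual_norm = fit@residualNorm,
         converged = fit@converged)
  } else stop("unsupported fit object")
}

#' Serialize a fit result to JSON
#'
#' Writes parameter values, fixed flags, approximate standard errors, residual
#' norm and convergence status.
#'
#' @param fit an \code{\linkS4class{AutoFit}}, \code{\linkS4class{CrossFit}}
#'   or \code{\linkS4class{DoseResponseFit}}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeFitJson <- function(fit, path) {
  jsonlite::write_json(.fitToList(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the simulation ground truth sidecar
#'
#' JSON companion to a simulated trace: the full species list, observation
#' volume and simulation configuration.
#'
#' @param trace a simulated \code{\linkS4class{PhotonTrace}}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeGroundTruthJson <- function(trace, path) {
  stopifnot(is(trace, "PhotonTrace"))
  pv <- trace@provenance
  if (is.null(pv$species))
    stop("trace carries no simulation ground truth")
  gt <- list(
    species = lapply(pv$species, function(s) list(
      label = s@label, count_mean = s@countMean, D_um2_s = s@D,
      brightness_green_cps = s@brightnessGreen,
      brightness_red_cps = s@brightnessRed,
      triplet_fraction = s@tripletFraction, triplet_time_s = s@tripletTime)),
    volume = list(omega_um = pv$volume@omega, z0_um = pv$volume@z0),
    config = list(box_um = pv$config@boxDimensions,
                  time_step_s = pv$config@timeStep,
                  duration_s = pv$config@duration,
                  bin_width_s = pv$config@binWidth,
                  background_green_cps = pv$config@backgroundGreen,
                  background_red_cps = pv$config@backgroundRed,
                  seed = pv$config@seed))
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
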