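#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn RootScanExperiment Dekadal forcing table (data.frame with
#'   year, month, tercile, label, ST, SM, V).
#' @param object A rootSSM object.
#' @export
setMethod("forcingData", "RootScanExperiment", function(object) {
  rd <- as.data.frame(rowData(object))
  rd$label <- dekadLabel(rd)
  rd
})

#' @describeIn RootScanExperiment The T x (S*C) production matrix
#'   (NA = missing).
#' @export
setMethod("productionAssay", "RootScanExperiment", function(object) {
  assay(object, "production")
})

#' @describeIn RootScanExperiment Long observation table
#'   (t, scanner, image, production), missing records omitted.
#' @export
setMethod("observationTable", "RootScanExperiment", function(object) {
  pr <- assay(object, "production")
  cd <- colData(object)
  out <- data.frame(
    t = rep(seq_len(nrow(pr)), times = ncol(pr)),
    scanner = rep(cd$scanner, each = nrow(pr)),
    image = rep(cd$image, each = nrow(pr)),
    production = as.vector(pr)
  )
  out <- out[!is.na(out$production), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$t, out$scanner, out$image), , drop = FALSE]
})

setMethod("show", "RootScanExperiment", function(object) {
  cd <- colData(object)
  cat("RootScanExperiment:", nrow(object), "dekadal periods x",
      ncol(object), "depth-wise images\n")
  cat("  scanners:", length(unique(cd$scanner)),
      " images per scanner:", length(unique(cd$image)), "\n")
  rd <- rowData(object)
  cat(sprintf("  period range: %s .. %s\n",
              dekadLabel(as.data.frame(rd))[1],
              dekadLabel(as.data.frame(rd))[nrow(object)]))
  pr <- assay(object, "production")
  cat(sprintf("  observed records: %d of %d (%.1f%% missing)\n",
              sum(!is.na(pr)), length(pr), 100 * mean(is.na(pr))))
  cat(sprintf("  ST range: %.1f..%.1f degC  SM range: %.1f..%.1f %%\n",
              min(rd$ST, na.rm = TRUE), max(rd$ST, na.rm = TRUE),
              min(rd$SM, na.rm = TRUE), max(rd$SM, na.rm = TRUE)))
  invisible(NULL)
})

#' @describeIn LatentTrajectory Scalar parameters of the trajectory.
#' @param object A rootSSM object.
#' @export
setMethod("trajectoryScalars", "LatentTrajectory",
          function(object) object@scalars)

#' @describeIn LatentTrajectory Standing root area path b_t, mm2 cm-2.
#' @export
setMethod("standingArea", "LatentTrajectory", function(object) object@b)

#' @describeIn LatentTrajectory Mean production path p_t, mm2 cm-2 day-1.
#' @export
setMethod("meanProductionPath", "LatentTrajectory", function(object) object@p)

setMethod("show", "LatentTrajectory", function(object) {
  s <- object@scalars
  cat("LatentTrajectory over", length(object@le), "periods\n")
  cat(sprintf("  b1=%.4g gamma=%.4g/day betaBase=%.4g/day stmin=%.2f degC\n",
              s@b1, s@gamma, s@betaBase, s@stmin))
  cat(sprintf("  b range: %.4g..%.4g mm2/cm2; p range: %.4g..%.4g mm2/cm2/day\n",
              min(object@b), max(object@b), min(object@p), max(object@p)))
  invisible(NULL)
})

setMethod("show", "ScalarParams", function(object) {
  cat(sprintf(paste0(
    "ScalarParams: b1=%.4g gamma=%.4g betaBase=%.4g stmin=%.2f\n",
    "  sigmaLe=%.3g sigmaSt=%.3g sigmaSm=%.3g\n"),
    object@b1, object@gamma, object@betaBase, object@stmin,
    object@sigmaLe, object@sigmaSt, object@sigmaSm))
  invisible(NULL)
})

#' @describeIn PosteriorDraws Draws of one parameter by base name.
#' @param name Parameter base name.
#' @export
setMethod("paramDraws", "PosteriorDraws", function(object, name) {
  cn <- colnames(object@draws)
  exact <- cn == name
  if (any(exact)) return(object@draws[, which(exact)[1]])
  idx <- grep(paste0("^", name, "\\["), cn)
  if (!length(idx)) stop("no parameter named '", name, "' in draws")
  sub <- object@draws[, idx, drop = FALSE]
  ord <- order(as.integer(sub("^.*\\[([0-9]+).*$", "\\1", colnames(sub))),
               suppressWarnings(
                 as.integer(sub("^.*,([0-9]+)\\]$", "\\1", colnames(sub)))))
  sub[, ord, drop = FALSE]
})

#' @describeIn PosteriorDraws Named split R-hat vector.
#' @export
setMethod("rhatValues", "PosteriorDraws", function(object) object@rhat)

#' @describeIn PosteriorDraws Chain of origin per draw.
#' @export
setMethod("chainIndex", "PosteriorDraws", function(object) object@chain)

#' @describeIn PosteriorDraws Per-draw observation-level log-likelihood
#'   matrix (draws x observations).
#' @export
setMethod("pointwiseLogLik", "PosteriorDraws",
          function(object) object@pointwiseLogLik)

setMethod("show", "PosteriorDraws", function(object) {
  cat("PosteriorDraws:", nrow(object@draws), "draws x",
      ncol(object@draws), "parameters (",
      length(unique(object@chain)), "chains )\n")
  cat(sprintf("  fixed stmin = %.2f degC; %d observations\n",
              object@stmin, nrow(object@obsKey)))
  if (length(object@rhat)) {
    bad <- sum(object@rhat > object@mcmc$rhatThreshold, na.rm = TRUE)
    cat(sprintf("  max split R-hat = %.3f (%d parameter(s) above %.2f)\n",
                max(object@rhat, na.rm = TRUE), bad,
                object@mcmc$rhatThreshold))
  }
  invisible(NULL)
})

#' @describeIn WaicResult The WAIC value.
#' @param object A rootSSM object.
#' @export
setMethod("waicValue", "WaicResult", function(object) object@waic)

setMethod("show", "WaicResult", function(object) {
  cat(sprintf("WAIC = %.3f (lppd = %.3f, pWaic = %.3f, n_obs = %d)\n",
              object@waic, object@lppd, object@pWaic,
              nrow(object@pointwise)))
  invisible(NULL)
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", nrow(object@forcing), "periods,",
      length(unique(object@observations$scanner)), "scanners x",
      length(unique(object@observations$image)), "images;",
      nrow(object@observations), "records\n")
  cat("  seed:", object@config$seed, "\n")
  invisible(NULL)
})
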