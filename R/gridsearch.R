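#' @include fit.R diagnostics.R
NULL

#' WAIC grid search for the minimum-temperature threshold
#'
#' The threshold enters the model through a step function of its own
#' value, which cripples gradient- and slice-based samplers, so it is
#' profiled instead of sampled: the model is refitted at each candidate
#' value (protocol default 0 to 10 degC in 0.1 degC steps, i.e. 101 fits)
#' and the value minimising WAIC is selected. Ties break toward the lower
#' threshold; per-point sampler failures are flagged and the scan
#' continues.
#'
#' @param rse A [RootScanExperiment-class].
#' @param gridLo,gridHi,step Grid bounds (degC) and spacing.
#' @param priors A [priorConfig()].
#' @param mcmc A [mcmcConfig()] used for every grid point; point i runs
#'   with seed \code{mcmc$seed + i}, so serial and process-parallel scans
#'   give identical results.
#' @param cores Independent processes over grid points
#'   (\code{parallel::mclapply}); 1 = serial.
#' @param keepFits Keep the per-point [PosteriorDraws-class] objects
#'   (memory-heavy; default discards them).
#' @return List with \code{bestStmin}, \code{profile} (data.frame: stmin,
#'   lppd, pWaic, waic, maxRhat, converged, failed) and, if requested,
#'   \code{fits}.
#' @export
gridSearchStmin <- function(rse, gridLo = 0, gridHi = 10, step = 0.1,
                            priors = priorConfig(), mcmc = mcmcConfig(),
                            cores = 1, keepFits = FALSE) {
  stopifnot(gridLo < gridHi, step > 0)
  grid <- seq(gridLo, gridHi, by = step)
  if (!length(grid)) stop("empty stmin grid")
  onePoint <- function(i) {
    m <- mcmc
    m$seed <- mcmc$seed + i
    res <- tryCatch({
      fit <- suppressWarnings(
        fitStateSpace(rse, stmin = grid[i], priors = priors, mcmc = m))
      w <- computeWaic(fit)
      list(lppd = w@lppd, pWaic = w@pWaic, waic = w@waic,
           maxRhat = max(rhatValues(fit), na.rm = TRUE),
           fit = if (keepFits) fit else NULL, failed = FALSE)
    }, error = function(e) {
      list(lppd = NA_real_, pWaic = NA_real_, waic = NA_real_,
           maxRhat = NA_real_, fit = NULL, failed = TRUE,
           message = conditionMessage(e))
    })
    res
  }
  results <- if (cores > 1)
    parallel::mclapply(seq_along(grid), onePoint, mc.cores = cores)
  else lapply(seq_along(grid), onePoint)
  profile <- data.frame(
    stmin = grid,
    lppd = vapply(results, `[[`, 0, "lppd"),
    pWaic = vapply(results, `[[`, 0, "pWaic"),
    waic = vapply(results, `[[`, 0, "waic"),
    maxRhat = vapply(results, `[[`, 0, "maxRhat"))
  profile$converged <- !is.na(profile$maxRhat) &
    profile$maxRhat <= mcmc$rhatThreshold
  profile$failed <- vapply(results, `[[`, TRUE, "failed")
  if (all(profile$failed)) stop("every grid point failed to fit")
  ok <- which(!profile$failed)
  best <- ok[which.min(profile$waic[ok])] # seq is ascending: ties -> lower
  out <- list(bestStmin = grid[best], profile = profile)
  if (keepFits) out$fits <- lapply(results, `[[`, "fit")
  out
}
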