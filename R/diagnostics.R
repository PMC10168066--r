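#' @include AllClasses.R
NULL

# coerce draws-by-chain input to a list of matrices
.chainList <- function(x) {
  if (inherits(x, "PosteriorDraws"))
    return(lapply(split(seq_len(nrow(x@draws)), x@chain),
                  function(i) x@draws[i, , drop = FALSE]))
  if (inherits(x, "mcmc.list")) return(lapply(x, as.matrix))
  if (is.list(x)) return(lapply(x, as.matrix))
  stop("expected a PosteriorDraws, mcmc.list, or list of chain matrices")
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed on split half-chains: each
#' chain is cut in half, and the ratio of pooled to within-chain variance
#' is evaluated across the 2m half-sequences. Values near 1 indicate
#' convergence; the model protocol flags parameters above 1.1.
#'
#' @param x A [PosteriorDraws-class], a \code{coda::mcmc.list}, or a list
#'   of per-chain draw matrices (same named columns).
#' @param method \code{"classic"} split R-hat, or \code{"rank"} for the
#'   rank-normalised variant.
#' @return Named numeric vector, one entry per parameter. Degenerate
#'   parameters (zero variance everywhere) return \code{NA}; chains stuck
#'   at different constants return \code{Inf}.
#' @export
computeRhat <- function(x, method = c("classic", "rank")) {
  method <- match.arg(method)
  chains <- .chainList(x)
  if (length(chains) < 2L)
    stop("split R-hat needs at least 2 chains")
  n0 <- unique(vapply(chains, nrow, 0L))
  if (length(n0) != 1L) stop("chains must have equal length")
  if (n0 < 4L) stop("need at least 4 draws per chain")
  half <- floor(n0 / 2)
  splits <- unlist(lapply(chains, function(m)
    list(m[seq_len(half), , drop = FALSE],
         m[seq.int(n0 - half + 1L, n0), , drop = FALSE])),
    recursive = FALSE)
  P <- ncol(chains[[1]])
  out <- vapply(seq_len(P), function(j) {
    xs <- lapply(splits, function(m) m[, j])
    if (method == "rank") {
      pooled <- unlist(xs)
      r <- rank(pooled, ties.method = "average")
      z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
      xs <- split(z, rep(seq_along(xs), each = half))
    }
    mns <- vapply(xs, mean, 0)
    vrs <- vapply(xs, var, 0)
    W <- mean(vrs)
    B <- half * var(mns)
    if (!is.finite(W) || W == 0) {
      if (is.finite(B) && B > 0) return(Inf)
      return(NA_real_)
    }
    sqrt(((half - 1) / half * W + B / half) / W)
  }, 0)
  names(out) <- colnames(chains[[1]])
  out
}

#' @importFrom stats qnorm
NULL

#' Widely applicable information criterion
#'
#' From a draws-by-points pointwise log-likelihood matrix:
#' \code{lppd = sum_i log mean_d exp(ll[d,i])} (log-sum-exp stabilised),
#' \code{pWaic = sum_i var_d(ll[d,i])} (n-1 denominator), and
#' \code{waic = -2 (lppd - pWaic)}.
#'
#' For a fitted model the pointwise set is, by default, the
#' \emph{conditional} factorisation: the image-level observation terms
#' plus the scanner-level latent-mean densities. The observation terms
#' alone (\code{level = "observation"}) are insensitive to the system
#' model here, because the scanner-level means and their free per-cell
#' dispersions can absorb any misfit of the production path — the
#' latent-level terms are what carry the threshold and trajectory
#' information into model comparison.
#'
#' @param x A [PosteriorDraws-class] or a draws x points matrix of
#'   log-likelihood values.
#' @param level For fits: \code{"conditional"} (observation + latent
#'   terms, default) or \code{"observation"}.
#' @return A [WaicResult-class].
#' @examples
#' computeWaic(matrix(c(-1, -3), 2, 1)) # lppd -1.5662, pWaic 2
#' @export
computeWaic <- function(x, level = c("conditional", "observation")) {
  level <- match.arg(level)
  pw <- if (inherits(x, "PosteriorDraws")) {
    if (level == "conditional" && length(x@latentLogLik))
      cbind(x@pointwiseLogLik, x@latentLogLik)
    else x@pointwiseLogLik
  } else as.matrix(x)
  if (!all(is.finite(pw)))
    stop("non-finite pointwise log-likelihood: an observation is ",
         "impossible under some draw")
  nd <- nrow(pw)
  mx <- apply(pw, 2, max)
  lppdI <- mx + log(colMeans(exp(sweep(pw, 2, mx)))) # log-sum-exp
  pWaicI <- apply(pw, 2, var)
  lppd <- sum(lppdI)
  pWaic <- sum(pWaicI)
  new("WaicResult", lppd = lppd, pWaic = pWaic,
      waic = -2 * (lppd - pWaic),
      pointwise = data.frame(lppd = lppdI, pWaic = pWaicI))
}

#' Posterior summary table
#'
#' Medians and central credible intervals for every monitored scalar and
#' every element of the latent paths. Deterministic given the draws.
#'
#' @param x A [PosteriorDraws-class] or a draws matrix with named columns.
#' @param quantiles Probabilities to report.
#' @return data.frame with one row per parameter: \code{parameter} (full
#'   coda-style name), \code{base}, \code{index} (first bracket index, NA
#'   for scalars), \code{mean}, quantile columns (\code{q2.5} etc.), and
#'   \code{rhat} when available.
#' @export
summarizePosterior <- function(x, quantiles = c(0.025, 0.25, 0.5,
                                                0.75, 0.975)) {
  draws <- if (inherits(x, "PosteriorDraws")) x@draws else as.matrix(x)
  qm <- t(apply(draws, 2, quantile, probs = quantiles, names = FALSE))
  colnames(qm) <- paste0("q", 100 * quantiles)
  out <- data.frame(parameter = colnames(draws),
                    base = sub("\\[.*$", "", colnames(draws)),
                    index = suppressWarnings(as.integer(
                      sub("^[^\\[]*\\[([0-9]+).*$", "\\1",
                          colnames(draws)))),
                    mean = colMeans(draws))
  out <- cbind(out, qm)
  if (inherits(x, "PosteriorDraws") && length(x@rhat))
    out$rhat <- x@rhat[out$parameter]
  rownames(out) <- NULL
  out
}
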