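#' @include model-math.R diagnostics.R
NULL

.qcols <- function(m, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  qm <- apply(m, 2, quantile, probs = probs, names = FALSE)
  qm <- if (length(probs) == 1L) matrix(qm, ncol = 1L) else t(qm)
  colnames(qm) <- paste0("q", 100 * probs)
  as.data.frame(qm)
}

#' Posterior series of derived environmental effects
#'
#' Computes, draw-wise and per period, the overall temperature effect
#' \eqn{\beta ext_t = \beta st_t + \beta sm_t SM_t}, the soil moisture
#' contribution \eqn{\beta sm_t SM_t}, and quantile summaries of the
#' coefficient, production, standing-area and growth-rate paths. All
#' derived quantities are evaluated per draw before summarising (a
#' functional of draws, not of marginal summaries).
#'
#' @param fit A [PosteriorDraws-class].
#' @param forcing Dekadal forcing data.frame the model was fitted on
#'   (e.g. \code{forcingData(rse)}).
#' @param probs Quantiles to report (default gives the median with 50%
#'   and 95% bands).
#' @return data.frame in long layout: \code{quantity} (betaExt,
#'   smContribution, betaSt, betaSm, le, p, b, beta), \code{t},
#'   \code{label}, and quantile columns.
#' @export
effectSeries <- function(fit, forcing,
                         probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  bst <- paramDraws(fit, "betaSt")
  bsm <- paramDraws(fit, "betaSm")
  T <- ncol(bst)
  stopifnot(nrow(forcing) == T)
  smc <- sweep(bsm, 2, forcing$SM, `*`)
  bext <- bst + smc
  pieces <- list(betaExt = bext, smContribution = smc, betaSt = bst,
                 betaSm = bsm, le = paramDraws(fit, "le"),
                 p = paramDraws(fit, "p"), b = paramDraws(fit, "b"),
                 beta = paramDraws(fit, "beta"))
  out <- do.call(rbind, lapply(names(pieces), function(nm) {
    cbind(data.frame(quantity = nm, t = seq_len(T),
                     label = dekadLabel(forcing)),
          .qcols(pieces[[nm]], probs))
  }))
  rownames(out) <- NULL
  out
}

#' Time-varying regression curves of production against temperature
#'
#' For each requested period, evaluates per draw the regression curve
#' \deqn{p(ST) = (e^{le_t} (ST - st_{min})^{\beta ext_t} + \beta_{base})
#'   b_t} for \eqn{ST > st_{min}} (and \eqn{\beta_{base} b_t} below the
#' threshold), then summarises across draws. At the period's observed
#' temperature the curve reproduces the fitted production draws exactly.
#'
#' @param fit A [PosteriorDraws-class].
#' @param forcing Dekadal forcing data.frame.
#' @param periods Period indices to evaluate (default all).
#' @param STgrid Temperature grid, degC.
#' @param probs Quantiles to report.
#' @param eps Threshold guard, degC.
#' @return data.frame: \code{t}, \code{label}, \code{ST}, quantile
#'   columns.
#' @export
regressionCurves <- function(fit, forcing,
                             periods = seq_len(nrow(forcing)),
                             STgrid = seq(0, 30, by = 0.5),
                             probs = c(0.25, 0.5, 0.75),
                             eps = .DEFAULT_EPS) {
  le <- paramDraws(fit, "le")
  bst <- paramDraws(fit, "betaSt")
  bsm <- paramDraws(fit, "betaSm")
  b <- paramDraws(fit, "b")
  betaBase <- paramDraws(fit, "betaBase")
  stmin <- fit@stmin
  out <- lapply(periods, function(t) {
    curves <- vapply(STgrid, function(st) {
      if (st > stmin + eps) {
        bext <- bst[, t] + bsm[, t] * forcing$SM[t]
        (exp(le[, t]) * (st - stmin)^bext + betaBase) * b[, t]
      } else betaBase * b[, t]
    }, numeric(nrow(le)))
    cbind(data.frame(t = t, label = dekadLabel(forcing)[t], ST = STgrid),
          .qcols(curves, probs))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percent production change per 1% soil moisture increase
#'
#' A one-percentage-point increase in soil moisture multiplies the
#' exogenous production term by \eqn{(ST - st_{min})^{\beta sm}}, so the
#' relative change is \code{100 * ((ST - stmin)^betaSm - 1)} (the additive
#' baseline \eqn{\beta_{base}} is neglected; it is orders of magnitude
#' below growing-season production). Set \code{exact = TRUE} to include
#' it, which requires the remaining state at the period.
#'
#' @param betaSm Interaction coefficient (scalar or draws).
#' @param ST Soil temperature, degC; must exceed \code{stmin + eps}.
#' @param stmin Threshold, degC.
#' @param eps Threshold guard, degC.
#' @param exact Include the baseline term.
#' @param le,betaSt,SM,betaBase State needed for \code{exact = TRUE}.
#' @return Percent change per +1 percentage point of soil moisture.
#' @examples
#' percentChangePerSM(0.05, 14, 4) # ~12.2%
#' @export
percentChangePerSM <- function(betaSm, ST, stmin, eps = .DEFAULT_EPS,
                               exact = FALSE, le = NULL, betaSt = NULL,
                               SM = NULL, betaBase = NULL) {
  if (any(ST <= stmin + eps))
    stop("percentChangePerSM: ST must exceed stmin + eps")
  if (!exact) return(100 * ((ST - stmin)^betaSm - 1))
  stopifnot(!is.null(le), !is.null(betaSt), !is.null(SM),
            !is.null(betaBase))
  ex0 <- exp(le) * (ST - stmin)^(betaSt + betaSm * SM)
  ex1 <- exp(le) * (ST - stmin)^(betaSt + betaSm * (SM + 1))
  100 * ((ex1 + betaBase) / (ex0 + betaBase) - 1)
}

# local maxima of a series with a minimum separation, greedy by height
.findPeaks <- function(x, minSep = 3) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) x[i - 1] else -Inf
    r <- if (i < n) x[i + 1] else -Inf
    x[i] > l && x[i] >= r
  }, TRUE))
  cand <- cand[order(-x[cand])]
  keep <- integer()
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= minSep))
      keep <- c(keep, i)
  sort(keep)
}

#' Production time-series report
#'
#' Per-period posterior median and 50%/95% credible bands of mean fine
#' root production, the mean of the observed records per period, and the
#' local production peaks per year (maxima of the posterior-median series
#' separated by at least \code{minPeakSep} periods).
#'
#' @param fit A [PosteriorDraws-class].
#' @param rse The fitted [RootScanExperiment-class].
#' @param minPeakSep Minimum period separation between reported peaks.
#' @return List with \code{table} (t, label, year, quantiles of p,
#'   observed mean) and \code{peaks} (year, t, label, median production).
#' @export
productionReport <- function(fit, rse, minPeakSep = 3) {
  forcing <- forcingData(rse)
  p <- paramDraws(fit, "p")
  tab <- cbind(data.frame(t = seq_len(nrow(forcing)),
                          label = forcing$label, year = forcing$year),
               .qcols(p))
  pr <- productionAssay(rse)
  tab$obsMean <- rowMeans(pr, na.rm = TRUE)
  tab$obsMean[is.nan(tab$obsMean)] <- NA_real_
  peaks <- do.call(rbind, lapply(split(tab, tab$year), function(d) {
    idx <- .findPeaks(d$q50, minSep = minPeakSep)
    if (!length(idx)) return(NULL)
    data.frame(year = d$year[idx], t = d$t[idx], label = d$label[idx],
               median = d$q50[idx])
  }))
  rownames(peaks) <- NULL
  list(table = tab, peaks = peaks)
}

#' Plot the production series with credible bands
#'
#' Posterior median (black), 50% and 95% bands (grey), observed per-period
#' means (red).
#'
#' @param report Output of [productionReport()].
#' @return A ggplot object.
#' @export
plotProduction <- function(report) {
  tab <- report$table
  ggplot2::ggplot(tab, ggplot2::aes(x = t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q2.5, ymax = q97.5),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q25, ymax = q75),
                         fill = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = q50), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = obsMean), colour = "red",
                       na.rm = TRUE) +
    ggplot2::labs(x = "dekadal period",
                  y = expression(paste("fine root production (",
                                       mm^2, " ", cm^-2, " ",
                                       day^-1, ")"))) +
    ggplot2::theme_minimal()
}

#' Plot the overall temperature effect and the moisture contribution
#'
#' @param es Output of [effectSeries()].
#' @return A ggplot object.
#' @export
plotEffectSeries <- function(es) {
  d <- es[es$quantity %in% c("betaExt", "smContribution"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = t, colour = quantity,
                                  fill = quantity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q25, ymax = q75),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = q50)) +
    ggplot2::scale_colour_manual(
      values = c(betaExt = "black", smContribution = "blue"),
      aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "dekadal period", y = "effect on log production") +
    ggplot2::theme_minimal()
}

#' Plot time-varying regression curves
#'
#' Median production against temperature per period, coloured by day of
#' year, with the threshold marked.
#'
#' @param rc Output of [regressionCurves()].
#' @param stmin Threshold to mark, degC.
#' @return A ggplot object.
#' @export
plotRegressionCurves <- function(rc, stmin = NULL) {
  g <- ggplot2::ggplot(rc, ggplot2::aes(x = ST, y = q50, group = t,
                                        colour = t)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "soil temperature (degC)",
                  y = "median production") +
    ggplot2::theme_minimal()
  if (!is.null(stmin))
    g <- g + ggplot2::geom_vline(xintercept = stmin, linetype = 2)
  g
}
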