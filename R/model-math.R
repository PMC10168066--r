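#' @include AllClasses.R
NULL

# Threshold guard: the exogenous term log(ST - stmin) is singular at
# equality, so the "above threshold" regime requires ST > stmin + eps.
# 0.01 degC is negligible against the 0.1 degC grid resolution of the
# threshold search.
.DEFAULT_EPS <- 0.01

#' Overall temperature effect
#'
#' The exponent of the temperature response,
#' \eqn{\beta ext_t = \beta st_t + \beta sm_t \times SM_t}: the independent
#' temperature coefficient plus the temperature-moisture interaction scaled
#' by volumetric soil moisture (raw percent).
#'
#' @param betaSt Independent temperature effect coefficient.
#' @param betaSm Temperature-moisture interaction coefficient.
#' @param SM Volumetric soil moisture, percent; >= 0.
#' @return \code{betaSt + betaSm * SM}, vectorised.
#' @examples
#' overallTemperatureEffect(1.0, 0.05, 20) # 2.0
#' @export
overallTemperatureEffect <- function(betaSt, betaSm, SM) {
  stopifnot(all(SM >= 0))
  betaSt + betaSm * SM
}

#' Exogenous temperature effect on the log growth rate
#'
#' \eqn{ex_t = \beta ext_t \log(ST_t - st_{min})}, defined only strictly
#' above the threshold. Callers must route periods with
#' \code{ST <= stmin + eps} to the below-threshold branch (see
#' [growthRate()]).
#'
#' @param betaExt Overall temperature effect (see
#'   [overallTemperatureEffect()]).
#' @param ST Soil temperature, degC.
#' @param stmin Minimum temperature threshold, degC.
#' @param eps Threshold guard, degC.
#' @return \code{betaExt * log(ST - stmin)}, vectorised.
#' @examples
#' exogenousEffect(1.5, 14, 4) # 1.5 * log(10)
#' @export
exogenousEffect <- function(betaExt, ST, stmin, eps = .DEFAULT_EPS) {
  if (any(ST <= stmin + eps))
    stop("exogenousEffect: ST must exceed stmin + eps; ",
         "route below-threshold periods to the baseline branch")
  betaExt * log(ST - stmin)
}

#' Instantaneous growth rate of standing root area
#'
#' Combines the latent other-factor path and the exogenous temperature
#' response into the growth rate
#' \deqn{\beta_t = \exp(le_t + ex_t) + \beta_{base}, \quad ST_t > st_{min};
#'   \qquad \beta_t = \beta_{base} \ otherwise,}
#' so the response term is switched off below the temperature threshold and
#' the rate never falls below the baseline.
#'
#' @param le Latent other-factor value (log scale).
#' @param betaSt,betaSm,SM See [overallTemperatureEffect()].
#' @param ST Soil temperature, degC.
#' @param stmin Threshold, degC.
#' @param betaBase Baseline growth rate, day-1; >= 0.
#' @param eps Threshold guard, degC.
#' @return Growth rate, day-1, vectorised over periods.
#' @examples
#' growthRate(0, 1, 0, 20, exp(1) + 4, 4, 0.001) # exp(1) + 0.001
#' @export
growthRate <- function(le, betaSt, betaSm, SM, ST, stmin, betaBase,
                       eps = .DEFAULT_EPS) {
  stopifnot(betaBase >= 0)
  above <- ST > stmin + eps
  resp <- numeric(length(ST))
  if (any(above)) {
    bext <- overallTemperatureEffect(betaSt, betaSm, SM)
    # recycle scalar-or-path arguments against ST
    leA <- rep_len(le, length(ST))[above]
    bextA <- rep_len(bext, length(ST))[above]
    resp[above] <- exp(leA + bextA * log(ST[above] - stmin))
  }
  resp + betaBase
}

#' Mean fine root production
#'
#' \eqn{p_t = \beta_t b_t}: production per unit soil-profile area is growth
#' rate times standing root area.
#'
#' @param beta Growth rate, day-1; >= 0.
#' @param b Standing root area, mm2 cm-2; > 0.
#' @return Production, mm2 cm-2 day-1.
#' @export
meanProduction <- function(beta, b) {
  stopifnot(all(beta >= 0), all(b > 0))
  beta * b
}

#' One mass-balance step of standing root area
#'
#' \eqn{b_t = b_{t-1} + pv_{t-1} - mv_{t-1}} with production
#' \eqn{pv = \beta b V} and mortality \eqn{mv = \gamma b V}, i.e.
#' \code{b_prev * (1 + (beta_prev - gamma) * V_prev)}.
#'
#' @param bPrev Standing root area at the previous period, mm2 cm-2; > 0.
#' @param betaPrev Growth rate at the previous period, day-1.
#' @param gamma Mortality rate, day-1.
#' @param VPrev Interval length of the previous period, days; > 0.
#' @return Standing root area at the next period.
#' @section Errors: An inadmissible combination with multiplier
#'   \code{1 + (beta - gamma) * V <= 0} signals an error (class
#'   \code{"rootSSM_positivity"}); samplers reject such proposals.
#' @examples
#' propagateBiomass(1, 0.01, 0.005, 10) # 1.05
#' @export
propagateBiomass <- function(bPrev, betaPrev, gamma, VPrev) {
  stopifnot(all(bPrev > 0), all(VPrev > 0))
  mult <- 1 + (betaPrev - gamma) * VPrev
  if (any(mult <= 0)) {
    cond <- structure(
      class = c("rootSSM_positivity", "error", "condition"),
      list(message = sprintf(
        "mass-balance positivity violated: 1 + (beta - gamma) * V = %.4g <= 0",
        min(mult)), call = sys.call(-1)))
    stop(cond)
  }
  bPrev * mult
}

#' Deterministic latent trajectory implied by coefficient paths
#'
#' Runs the mass-balance recursion over the forcing series: given the three
#' coefficient paths, the growth rate, standing root area and mean
#' production series are computed exactly (the system model contains no
#' innovation term on b_t, so b is computed, never sampled).
#'
#' @param forcing Dekadal forcing data.frame (columns \code{ST}, \code{SM},
#'   \code{V}; see [aggregateToDekads()]).
#' @param le,betaSt,betaSm Coefficient paths of length \code{nrow(forcing)}.
#' @param scalars A [ScalarParams-class] (uses b1, gamma, betaBase, stmin).
#' @param eps Threshold guard, degC.
#' @return A [LatentTrajectory-class].
#' @section Errors: Propagates the positivity violation of
#'   [propagateBiomass()], reporting the offending period index.
#' @export
biomassTrajectory <- function(forcing, le, betaSt, betaSm, scalars,
                              eps = .DEFAULT_EPS) {
  T <- nrow(forcing)
  stopifnot(T >= 2, length(le) == T, length(betaSt) == T,
            length(betaSm) == T)
  beta <- growthRate(le, betaSt, betaSm, forcing$SM, forcing$ST,
                     scalars@stmin, scalars@betaBase, eps)
  b <- numeric(T)
  b[1] <- scalars@b1
  for (t in 2:T) {
    b[t] <- tryCatch(
      propagateBiomass(b[t - 1], beta[t - 1], scalars@gamma,
                       forcing$V[t - 1]),
      rootSSM_positivity = function(e) {
        cond <- structure(
          class = c("rootSSM_positivity", "error", "condition"),
          list(message = sprintf("%s (at period index %d)",
                                 conditionMessage(e), t),
               call = NULL))
        stop(cond)
      })
  }
  p <- meanProduction(beta, b)
  new("LatentTrajectory", le = le, betaSt = betaSt, betaSm = betaSm,
      b = b, p = p, scalars = scalars)
}

#' Growth-rate path of a trajectory
#'
#' Recomputes \eqn{\beta_t} from a [LatentTrajectory-class] and its forcing.
#'
#' @param traj A [LatentTrajectory-class].
#' @param forcing The forcing data.frame the trajectory was built on.
#' @param eps Threshold guard, degC.
#' @return Numeric vector of growth rates, day-1.
#' @export
growthRatePath <- function(traj, forcing, eps = .DEFAULT_EPS) {
  s <- traj@scalars
  growthRate(traj@le, traj@betaSt, traj@betaSm, forcing$SM, forcing$ST,
             s@stmin, s@betaBase, eps)
}
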