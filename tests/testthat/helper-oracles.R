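# Independent naive-loop oracles. Deliberately unvectorised and composed
# from the model definition directly, so they share no code path with the
# package implementations they check.

naiveLogPosterior <- function(q, fo, obs, stmin, pr) {
  T <- nrow(fo)
  S <- ncol(q$ps)
  halfn <- function(x, sd, lower = 0, upper = Inf) {
    dnorm(x, 0, sd, log = TRUE) -
      log(pnorm(upper, 0, sd) - pnorm(lower, 0, sd))
  }
  beta <- numeric(T)
  for (t in 1:T) {
    if (fo$ST[t] > stmin + pr$eps) {
      bext <- q$betaSt[t] + q$betaSm[t] * fo$SM[t]
      beta[t] <- exp(q$le[t] + bext * log(fo$ST[t] - stmin)) + q$betaBase
    } else beta[t] <- q$betaBase
  }
  b <- numeric(T)
  b[1] <- q$b1
  for (t in 2:T) {
    mult <- 1 + (beta[t - 1] - q$gamma) * fo$V[t - 1]
    if (mult <= 0) return(list(logPost = -Inf))
    b[t] <- b[t - 1] * mult
  }
  p <- beta * b
  ll <- 0
  for (t in 1:T) for (s in 1:S) {
    lamT <- 1 / (q$cvT[t]^2 * p[t])
    ll <- ll + dgamma(q$ps[t, s], shape = lamT * p[t], rate = lamT,
                      log = TRUE)
  }
  pw <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    t <- obs$t[i]; s <- obs$scanner[i]
    lamS <- 1 / (q$cvS[t, s]^2 * q$ps[t, s])
    pw[i] <- dgamma(obs$production[i], shape = lamS * q$ps[t, s],
                    rate = lamS, log = TRUE)
    ll <- ll + pw[i]
  }
  lp <- dnorm(q$le[1], pr$le1Mean, pr$le1Sd, log = TRUE) +
    dnorm(q$betaSt[1], 0, pr$coef1Sd, log = TRUE) +
    dnorm(q$betaSm[1], 0, pr$coef1Sd, log = TRUE)
  for (t in 2:T) {
    lp <- lp + dnorm(q$le[t], q$le[t - 1], q$sigmaLe, log = TRUE) +
      dnorm(q$betaSt[t], q$betaSt[t - 1], q$sigmaSt, log = TRUE) +
      dnorm(q$betaSm[t], q$betaSm[t - 1], q$sigmaSm, log = TRUE)
  }
  lp <- lp + halfn(q$gamma, pr$gammaSd, 0, pr$gammaUpper) +
    halfn(q$betaBase, pr$betaBaseSd, pr$betaBaseLower) +
    dnorm(q$b1, pr$b1Mean, pr$b1RelSd * pr$b1Mean, log = TRUE) -
    log(1 - pnorm(0, pr$b1Mean, pr$b1RelSd * pr$b1Mean)) +
    halfn(q$sigmaLe, pr$sigmaSd, pr$sigmaLower) +
    halfn(q$sigmaSt, pr$sigmaSd, pr$sigmaLower) +
    halfn(q$sigmaSm, pr$sigmaSd, pr$sigmaLower)
  for (t in 1:T) lp <- lp + halfn(q$cvT[t], pr$cvSd, pr$cvLower)
  for (t in 1:T) for (s in 1:S)
    lp <- lp + halfn(q$cvS[t, s], pr$cvSd, pr$cvLower)
  list(logPost = ll + lp, pointwise = pw)
}

# two-pass WAIC, direct formulas, no stabilisation
naiveWaic <- function(pw) {
  lppd <- 0; pw2 <- 0
  for (i in seq_len(ncol(pw))) {
    lppd <- lppd + log(mean(exp(pw[, i])))
    m <- mean(pw[, i])
    pw2 <- pw2 + sum((pw[, i] - m)^2) / (nrow(pw) - 1)
  }
  list(lppd = lppd, pWaic = pw2, waic = -2 * (lppd - pw2))
}
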