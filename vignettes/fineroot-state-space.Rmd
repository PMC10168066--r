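---
title: "A state-space model of fine root production under soil temperature and moisture forcing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A state-space model of fine root production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootSSM)
```

## The scientific problem

Fine roots — the absorptive root fraction that takes up water and
nutrients — are observed in situ by repeatedly imaging the same soil
profile with buried flatbed scanners (an approach analogous to
minirhizotrons). Tracing newly grown root area between consecutive scans
yields *fine root production* (mm² of new root area per cm² of profile per
day) for each depth-wise image within each scanner. The ecological
question is how this production responds to soil temperature and soil
moisture, and crucially whether that response itself changes through the
season and between years (temperature hysteresis: a different response at
the same temperature in the warming and the cooling phase of the year).
Ordinary regression assumes a constant coefficient and cannot express
this; rootSSM implements a Bayesian state-space model with time-varying
coefficients instead.

## The system model

Time runs in dekads: each month is split into days 1–10, 11–20 and 21–end,
giving 36 periods per year with interval lengths $V_t \in \{8,9,10,11\}$
days. Daily sensor series are averaged within dekads.

Mean production is growth rate times standing root area,
$$p_t = \beta_t b_t,$$
and standing root area follows a deterministic mass balance
$$b_t = b_{t-1} + p_{t-1} V_{t-1} - \gamma\, b_{t-1} V_{t-1},$$
with a constant mortality rate $\gamma$ (day⁻¹). The recursion has no
innovation term, so $b_t$ is *computed*, never sampled — given $b_1$,
$\gamma$ and the coefficient paths it is exact to machine precision, and
the package enforces the admissibility condition
$1 + (\beta_t - \gamma) V_t > 0$ (violations are rejected with $-\infty$
log posterior rather than clamped, keeping the mass balance exact).

The growth rate switches regimes at a minimum soil temperature threshold
$st_{min}$:
$$\beta_t = \begin{cases}
 \exp(le_t + \beta ext_t \log(ST_t - st_{min})) + \beta_{base}, &
   ST_t > st_{min} \\
 \beta_{base}, & ST_t \le st_{min},
\end{cases}$$
where $\beta_{base}$ is a small baseline ("system noise" growth persisting
through dormancy), $le_t$ captures all non-modelled influences (internal
carbon storage, nutrient status, mycorrhizae), and the overall temperature
effect decomposes as
$$\beta ext_t = \beta st_t + \beta sm_t \times SM_t,$$
an independent temperature coefficient plus a temperature × moisture
interaction. Soil moisture has deliberately no main effect: watering
frozen soil does not grow roots, so moisture only modulates the
temperature response. $SM_t$ enters in raw percent, $ST_t$ in °C, $V_t$ in
days.

The three paths $le_t$, $\beta st_t$, $\beta sm_t$ evolve as Gaussian
random walks — the weakest assumption about temporal change that still
borrows strength across neighbouring periods.

Because $\log(ST_t - st_{min})$ is singular at equality, the
above-threshold branch requires $ST_t > st_{min} + \varepsilon$ with
$\varepsilon = 0.01$ °C — negligible against the 0.1 °C resolution of the
threshold search, but it removes the singularity. The regime switch is
continuous in effect: as $ST_t \downarrow st_{min}$ with a positive
exponent, the response term vanishes and $\beta_t \to \beta_{base}$, which
the tests assert numerically.

## The observation model

Errors have two levels. Scanner-level means scatter around the stand-level
state,
$$ps_{t,s} \sim \mathrm{Gamma}(\lambda_t\, p_t,\ \lambda_t),$$
(mean $p_t$ by construction), and image-level observations scatter around
their scanner,
$$F_{t,s,c} \sim \mathrm{Gamma}(\lambda s_{t,s}\, ps_{t,s},\ \lambda s_{t,s}).$$
Missing records — scanner failures are common in buried hardware — simply
contribute nothing. Records of exactly zero lie outside gamma support and
are treated as left-censored at $\delta$ = half the smallest positive
record (the likelihood uses the gamma CDF at $\delta$); an additive-offset
alternative is available via `priorConfig(zeroRule = "offset")`. Censoring
was chosen as the default because it preserves the mean structure, while
an offset biases every zero upward.

### Dispersion parameterisation

The sampler parameterises the gamma levels by their coefficient of
variation: $\lambda_t = 1/(cv_t^2\, p_t)$ so that the shape is
$1/cv_t^2$, and likewise per (period, scanner) at the image level. This is
an exact reparameterisation of the same model (the mean structure is
untouched and $\lambda$ is recoverable from any draw), but it is much
better behaved numerically: with $\lambda$ parameterised directly, winter
periods with $p_t \approx \beta_{base} b_t \sim 10^{-4}$ drive the shape
$\lambda_t p_t$ below 1, where the gamma density has an infinite spike at
zero and slice samplers stall. The cv form keeps shapes at $1/cv^2$
regardless of the production scale. Priors are half-Normal(0, 0.25) on
each cv, truncated below at 0.01 to exclude a degenerate noise-free
observation model. The prior scale matters beyond taste: replicate CVs
above ~60 % would mean depth-wise images of the same scanner disagreeing
by more than half their value, contrary to the measurement design, and —
more importantly for inference — cv values above 1 put the gamma levels
in the small-shape regime whose density spikes at zero, where latent
means far below their expectation become nearly free. In that regime the
observation hierarchy can absorb arbitrary system-model misfit and the
threshold search loses its signal; keeping shapes of order one or larger
preserves it.

Whether $\lambda s$ is free per (period, scanner) or shared is not
determined by the data structure; it is kept free per (t, s) to match the
model's indexing, at the price of weak identification with only C images
per scanner — the proper prior bounds it.

## Priors

All priors are weakly informative defaults of this implementation, are
fully configurable through `priorConfig()`, and are *not* a reproduction
of the original study's prior table:

| parameter | prior | default rationale |
|---|---|---|
| $\gamma$ | half-Normal(0, 0.05), truncated to (0, 0.09) | turnover faster than ~11 days is implausible; the bound also guarantees mass-balance positivity for every dekad length |
| $\beta_{base}$ | half-Normal(0, 0.01) | dormant-season growth is orders below peak rates |
| $b_1$ | Normal($m$, 0.5$m$) truncated positive | $m$ = standing root area on the first image when known |
| $\sigma_{le}, \sigma_{st}, \sigma_{sm}$ | half-Normal(0, 1) | random-walk steps are per-dekad changes |
| $cv$ (both levels) | half-Normal(0, 0.25) | replicate scatter of tens of percent; shapes stay O(1) (see above) |
| $le_1$ | Normal(−5, 5²) | log scale; spans tiny to order-one responses |
| $\beta st_1, \beta sm_1$ | Normal(0, 1) | exponents of order one |

## Inference

The threshold $st_{min}$ is a parameter inside a step function of itself,
which cripples samplers; it is therefore profiled, not sampled: the model
is refitted over a grid (protocol default 0–10 °C in 0.1 °C steps, 101
fits) and the fit minimising WAIC is selected, ties breaking toward the
lower threshold. Per-point failures are flagged and the scan continues.

Sampling follows the study protocol: four chains of 30,000 iterations
including 10,000 warmup, post-warmup draws thinned to 20 % (every 5th
draw, giving exactly 16,000 retained draws), convergence assessed by split
$\hat R \le 1.1$. `computeRhat()` implements split-$\hat R$ directly
(classic by default, rank-normalised optionally). The draw engine is JAGS
(slice/Gibbs updates) via rjags; the joint density it targets is the same
one `logPosterior()` computes in plain R, and the latter is unit-tested
against an independent naive-loop oracle at 1e-10. The random walks are
sampled in their natural centred parameterisation — non-centring is a
geometry fix for gradient-based samplers and brings nothing to
conditional one-site updates.

The WAIC pointwise unit deserves care in this model. Using only the
image-level observation terms looks like the natural predictive
factorisation, but it is *insensitive to the system model*: the
scanner-level means $ps_{t,s}$ and their free per-cell dispersions can
reproduce the observed records regardless of where the production path
$p_t$ sits, so an image-level-only WAIC profile over $st_{min}$ is flat
to Monte-Carlo noise — we verified this empirically (grid argmins were
essentially uniform over the grid). `computeWaic()` therefore defaults to
the conditional factorisation, adding the scanner-level latent densities
$\log \Gamma(ps_{t,s} \mid \lambda_t p_t, \lambda_t)$ to the pointwise
set; these are the terms through which the threshold and the trajectory
inform model comparison. The observation-only variant remains available
(`level = "observation"`). The variance form
$p_{waic} = \sum_i \mathrm{Var}_d\, ll_{d,i}$ uses the $n-1$ denominator;
lppd is computed with log-sum-exp stabilisation.

## The synthetic-data generator

`makeSyntheticStudy()` builds complete studies with the exact statistical
structure the model assumes, so inference can be validated by parameter
recovery without any field data. Daily soil temperature is a seasonal
sinusoid (defaults: mean 15.5 °C, amplitude 12 °C, phase 110 d, noise sd
1.2 °C → winter minima ≈ 2–5 °C, summer maxima ≈ 26–28 °C); daily soil
moisture is a 12 % baseline plus exponentially decaying pulses at Poisson
times (rate 0.12 d⁻¹, mean magnitude 8 %, decay 0.08 d⁻¹ → a 12–40 %
range). These emulate a temperate-forest site and are this package's
defaults, not field data.

The default ground truth is $\gamma = 0.005$ d⁻¹, $\beta_{base} = 10^{-4}$
d⁻¹, $st_{min} = 4$ °C, $b_1 = 1$ mm² cm⁻², smooth sinusoidal coefficient
paths $\beta st_t \in [0.5, 1.5]$ and $\beta sm_t \in [0, 0.06]$ peaking
in spring, and 30 % coefficients of variation at both observation levels
with 5 % missingness. One generator choice deserves emphasis: the baseline
of the latent path $le_t$ is calibrated by bisection so that the standing
root area is annually balanced ($b_T \approx b_1$) — the quasi-steady
state a mature root system is in. Without this, the power-law growth term
integrates to either exponential explosion or collapse for almost any
hand-picked constant, which no field system shows.

What the generator does *not* emulate: spatially correlated scanners,
depth-dependent production, mechanistic post-installation disturbance
(handled only as an exclusion filter in preprocessing), and
autocorrelated sensor noise. Passing recovery tests therefore demonstrate
correctness of the inference machinery under the model's own assumptions,
not robustness to real-data misspecification.

## Preprocessing choices

Scan intervals rarely align with dekad boundaries. Each interval's rate is
attributed to the dekads it overlaps, weighted by overlapping days, which
conserves time-integrated production exactly (tested at 1e-9); the
original study states only that series were "recalculated" to dekads, so
overlap weighting is this package's choice. Dekads without coverage stay
missing — never imputed, never zero. Records within the stand-specific
post-installation disturbance window (defaults 307 days cypress, 68 days
oak) are dropped before aggregation. Scan gaps above 45 days warn but are
still attributed.

## Numerical choices and degenerate inputs

* Threshold guard ε = 0.01 °C; below-threshold periods bypass the
  logarithm entirely (the indicator is data once $st_{min}$ is fixed).
* Positivity violations reject with $-\infty$ rather than clamp; in the
  JAGS graph the same region is excluded by the γ truncation.
* Zero-variance degenerate cases: constant chains return $\hat R$ = NA
  (all equal) or Inf (distinct constants) rather than crashing; zero
  random-walk sd is excluded by a 1e-4 truncation.
* WAIC errors on any non-finite pointwise column (an impossible
  observation) instead of silently propagating -Inf.
* Ties in the WAIC profile break toward the lower threshold,
  deterministically.
* Grid-scan parallelism (`cores > 1`) assigns grid point *i* the seed
  `seed + i`, so serial and parallel scans are identical.

## Problem sizes used in the validation suite

The packaged recovery study uses 2 years × 3 scanners × 4 images
(T = 72, ≈ 820 records), fitted with 4 × 2,000-iteration chains (1,000
warmup) at the generating threshold, plus a coarse 1 °C grid scan with
2 × 1,400-iteration chains (600 warmup) per point. These sizes were chosen as the
smallest at which the recovery targets (credible-interval coverage of
γ and $\beta_{base}$, Pearson r > 0.9 on the production path, threshold
recovered within 1 °C) are comfortably met; the full protocol
(4 × 30,000 iterations, 0.1 °C grid) is what `mcmcConfig()` and
`gridSearchStmin()` default to.

## Known limitations

* $le_t$ and the exogenous term are only separated by their random-walk
  smoothness priors — at a single period only their sum is identified.
  Posterior uncertainty on the decomposition is honest but wide.
* $\lambda s_{t,s}$ with C ≈ 4 replicates is weakly identified (see
  above).
* WAIC differences between neighbouring grid points can be within
  Monte-Carlo error at short chain lengths; the packaged scan uses a
  coarse grid for exactly that reason.
* The percent-change-per-moisture summary neglects $\beta_{base}$
  (the exact variant is available behind `exact = TRUE`); at
  growing-season production the difference is far below posterior
  uncertainty.
* Below-threshold periods carry no information about $st_{min}$ from the
  likelihood gradient, only through the regime assignment; thresholds
  below every observed winter temperature are indistinguishable (a flat
  WAIC profile is the correct behaviour there).
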