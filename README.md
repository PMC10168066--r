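# rootSSM

Bayesian state-space modelling of fine root production from buried
flatbed-scanner (minirhizotron-style) time series.

## The problem

Repeatedly imaging the same forest soil profile yields fine root
production — new root area per unit profile area per day
(mm² cm⁻² day⁻¹) — for each depth-wise image *c* within each scanner *s*
at each observation time *t*. Ecologists want to know how production
responds to soil temperature and soil moisture, and whether that response
itself drifts through the season and between years (temperature
hysteresis). A fixed-coefficient regression cannot express this; rootSSM
fits a state-space model with **time-varying coefficients**.

## The model

Time runs in dekads (early/mid/late of each month, 36 per year, interval
lengths $V_t$ days). The system model is

$$p_t = \beta_t b_t, \qquad
  b_t = b_{t-1} + p_{t-1}V_{t-1} - \gamma\, b_{t-1} V_{t-1},$$

a deterministic mass balance for standing root area $b_t$ (mm² cm⁻²) with
constant mortality rate $\gamma$, and a threshold growth rate

$$\beta_t = \begin{cases}
  \exp\!\big(le_t + \beta ext_t \log(ST_t - st_{min})\big) + \beta_{base},
    & ST_t > st_{min}\\
  \beta_{base}, & ST_t \le st_{min},
\end{cases}
\qquad \beta ext_t = \beta st_t + \beta sm_t \, SM_t,$$

where the latent path $le_t$ and the coefficients
$\beta st_t, \beta sm_t$ evolve as Gaussian random walks. Observations
follow a two-level gamma hierarchy,
$ps_{t,s} \sim \Gamma(\lambda_t p_t, \lambda_t)$ and
$F_{t,s,c} \sim \Gamma(\lambda s_{t,s}\, ps_{t,s}, \lambda s_{t,s})$,
separating among-scanner from within-scanner error. The minimum growth
temperature $st_{min}$ is selected by refitting over a 0–10 °C grid and
minimising WAIC; sampling runs 4 × 30,000-iteration chains (10,000
warmup, thinned to 20 % → 16,000 draws) with split R̂ ≤ 1.1 as the
convergence criterion. See the vignette
(`vignettes/fineroot-state-space.Rmd`) for priors, parameterisation and
numerical choices.

## Worked example

Simulate a one-year synthetic study with known truth
(γ = 0.005 day⁻¹, β_base = 10⁻⁴ day⁻¹, st_min = 4 °C), fit it, and
summarise:

```r
library(rootSSM)
study <- makeSyntheticStudy(syntheticConfig(years = 1, S = 2, C = 2, seed = 7))
study@experiment
#> RootScanExperiment: 36 dekadal periods x 4 depth-wise images
#>   scanners: 2  images per scanner: 2
#>   period range: 2011-01-early .. 2011-12-late
#>   observed records: 131 of 144 (9.0% missing)
#>   ST range: 3.8..27.6 degC  SM range: 14.7..36.2 %

mc  <- mcmcConfig(chains = 2, iterations = 3000, warmup = 1000,
                  thinKeepFraction = 0.5, seed = 7, adapt = 500)
fit <- fitStateSpace(study@experiment, stmin = 4, mcmc = mc)

s <- summarizePosterior(fit)
s[s$parameter %in% c("gamma", "betaBase", "b1"),
  c("parameter", "q2.5", "q50", "q97.5")]
#>  parameter     q2.5      q50    q97.5
#>         b1 4.78e-01 0.590665 0.846132
#>   betaBase 9.03e-05 0.000135 0.000174
#>      gamma 4.23e-03 0.006287 0.010389

computeWaic(fit)
#> WAIC = -2725.269 (lppd = 1521.757, pWaic = 159.122, n_obs = 203)

productionReport(fit, study@experiment)$peaks
#>  year  t         label   median
#>  2011  2   2011-01-mid 9.43e-05
#>  2011 16 2011-06-early 2.29e-02
#>  2011 19 2011-07-early 7.54e-02
```

The 95 % credible intervals recover the generating scalars (γ:
[0.0042, 0.0104] around a truth of 0.005; β_base: [9.0 × 10⁻⁵,
1.7 × 10⁻⁴] around 10⁻⁴), the posterior-median production path
correlates with the generating path at r = 0.99, and the peak finder
locates the early-summer production maxima (the January "peak" is the
dormant-season baseline ripple, five hundred times smaller). The WAIC
point count (203) is the conditional factorisation: 131 image-level
records plus 72 scanner-level latent terms.
Units throughout: production mm² cm⁻² day⁻¹, rates day⁻¹, temperature °C,
moisture volumetric %.

For field data, the entry points are `aggregateToDekads()` (daily sensor
CSV → dekadal forcing), `excludeDisturbanceWindow()` +
`assignProductionToDekads()` (raw scan table → dekadal records),
`alignDataset()`, then `gridSearchStmin()` / `fitStateSpace()` and the
`effectSeries()` / `regressionCurves()` / `productionReport()`
summaries. A YAML-driven wrapper (`runSimulate`, `runFit`,
`runScanStmin`, `runReport`, with a thin CLI at
`inst/scripts/rootssm.R`) orchestrates the same stages.

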