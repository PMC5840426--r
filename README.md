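# roostSSM

Bayesian state-space modelling of monthly roost ("camp") counts for
highly mobile animals — flying-foxes being the motivating case — where
the fraction of the population available to be counted swings with
season and episodic cyclones perturb mortality, recruitment and
roosting behaviour at once. The package is for monitoring programmes
that count every known roost monthly and need a defensible total
abundance trend out of those noisy, partially observed totals.

## The model

Three log-normal layers, monthly time step:

- **Process** — total population `X_t ~ lnN(log(X_{t-1} exp(ρ_t − μ_t)), σ²_proc)`,
  with recruitment `ρ` acting over the December–February breeding
  season and mortality `μ` year-round.
- **Availability** — in-camp population `X_t^C ~ lnN(log(p_t X_t), σ²_camp)`
  where `p_t = (cos(2πt/12) + α₁)/α₂ · (1 − c_R I_C(t))` peaks in
  December and troughs in June.
- **Observation** — counted total `Y_t ~ lnN(log(X_t^C), σ²_obs)`;
  unsurveyed months simply contribute no observation term.

A cyclone multiplies mortality by `c_μ ≥ 1` and availability by
`1 − c_R` at impact, both decaying linearly to baseline over 12
months, and multiplies the next breeding season's recruitment by
`c_ρ ∈ (0,1)`. Inference is by an adaptive Metropolis-within-Gibbs
sampler (C++ core) with exact Gibbs draws of the latent paths,
Gelman–Rubin diagnostics, and derived posterior quantities: the yearly
exponential rate of increase `r` with and without cyclones,
`P(r < 0)`, November abundance summaries and forward projections. A
nonparametric drift-diffusion-jump analysis localizes perturbations in
the series as an early-warning companion. A full generative simulator
(`defaultScenario()`, `simulateScenario()`) reproduces the study's
monitoring conditions so everything is testable without field data.

## Worked example

```r
library(roostSSM)

# a 154-month synthetic monitoring series with three cyclones
d <- simulateScenario(defaultScenario(seed = 42))
d@counts
#> CountSeries: 154 months (154 observed)
#>   observed totals: median 98414, range 9441-770696

fit <- fitSSM(d@counts, d@scenario@schedule,
              McmcConfig(nChains = 3, nIter = 5000, nBurnin = 2000,
                         seed = 7))
fit
#> PosteriorDraws: 3 chains x 5000 iterations
#>   max Rhat: 1.037
#>   latent states stored at 500 iterations per chain

round(colMeans(paramMatrix(fit))[c("mu", "cMu", "cR")], 3)
#>    mu   cMu    cR
#> 0.022 4.650 0.323

rateOfIncrease(fit)
#> DerivedRates (15000 draws): r = -0.069/yr without cyclones,
#> -0.185/yr at 0.234 events/yr; P(r < 0) = 0.85
```

The fit converges (all potential scale reduction factors below 1.2)
and recovers the generative regime: background mortality near
0.017/month, a several-fold cyclone mortality pulse, a ~quarter drop
in availability at impact, and — at the observed cyclone frequency of
three events in 12.8 years — a posterior mean yearly rate of increase
of −0.19 with an 85% posterior probability of decline (this seed drew
a harsher-than-average noise sequence; the generative rate is −0.13).
November summaries and projections come from the stored latent states:

```r
nov <- novemberSummary(fit)
percentDecline(fit, nov$monthIndex[1], nov$monthIndex[nrow(nov)])
#> [1] 92.2   # median percent decline, first to last November

res <- ddj(d@counts)   # drift-diffusion-jump decomposition
res
#> DdjResult: 153 grid points, bandwidth 3.00 months, 253 clamped estimates
```

`jumpPeaks(res, 3)` returns the months of the three strongest
jump-intensity peaks; on series with injected single-month shocks
these land within ±2 months of the true perturbations.

A thin command-line wrapper over the same pipeline lives in
`inst/scripts/roostssm.R` (`simulate`, `fit`, `summarize`, `ddj`,
`project`), configured by flags or a YAML file.

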