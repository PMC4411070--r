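# pondSVC

Bayesian spatially varying coefficient (SVC) models for annual spring pond
abundance on a stratified aerial waterfowl-habitat survey.

Wetland ("pond") counts in the Prairie Pothole and Great Plains regions are
driven by seasonal precipitation and temperature, by the previous year's
water conditions, and by long-term land-use change — but the *importance* of
each driver varies across the region. Conventional regressions estimate one
coefficient per driver and so can badly misrepresent a non-stationary
system. pondSVC implements the SVC alternative for stratum-by-year pond
panels: every coefficient is a global mean plus a spatially correlated
stratum-level deviation.

## The model

Pond totals are lognormal with stratum-specific dispersion and a log-area
offset:

```
Pond[s,t] ~ LN(mu[s,t], tau[s])
mu[s,t]   = (mu0 + w0[s]) + sum_p (mu_beta[p] + W[s,p]) * x[s,t,p] + log(area[s])
```

Predictors: log ponds of the previous year (lag), a linear time trend, and
log total precipitation and mean daily-maximum temperature for the four
seasons preceding the late-May survey. The intercept deviations `w0` follow
a Gaussian process with an isotropic Gaussian kernel `exp(-phi0^2 d^2)`; the
coefficient deviations `W` share a separable matrix-normal prior
`MN(0, K_B(phiB), T)` with `T = diag(sigma_beta) %*% rho %*%
diag(sigma_beta)` — one spatial kernel for all predictors, one covariance
among predictors (equivalently, `vec(W) ~ MVN(0, K_B ⊗ T)`). Priors:
Normal(0, 10) means, Gamma(1.2, 0.2) scales, LKJ(1) (uniform) correlation,
and Uniform decay parameters bounded so the kernel spans correlations
0.90–0.01 across the observed inter-stratum distances.

Inference is a partially collapsed MCMC: the Gaussian layers are integrated
out analytically, the hyperparameters are sampled by adaptive Metropolis and
interweaved slice moves against that marginal likelihood, and the Gaussian
layer is redrawn exactly from its conditional every sweep. Derived outputs
— effective spatial ranges (`sqrt(-log(0.05))/phi`), a per-stratum variance
decomposition across drivers, and lognormal density/CV transforms — are
propagated draw-by-draw. See `vignettes/pondSVC-methods.Rmd` for the full
account.

## Worked example

A fully synthetic study (the generator emulates the survey's panel
structure; its default truth sits at published posterior medians — lag
0.259, winter precipitation 0.372, effective ranges 688/644 km):

```r
library(pondSVC)
sim <- simulateStudy(n_strata = 12, n_years = 30, seed = 1)
sim$panel
#> PondPanel: 12 strata x 30 years (1961-1990), first year = lag source
#>   predictors: lag, time, precip_summer, precip_fall, precip_winter,
#>     precip_spring, tmax_summer, tmax_fall, tmax_winter, tmax_spring

fit <- runMCMC(sim$panel, chains = 2, warmup = 200, kept = 200, seed = 42)
s <- posteriorSummary(fit)
subset(s, grepl("^mu_beta", parameter))
#>               parameter   median    ci_lo    ci_hi significant
#>            mu_beta[lag]  0.33319  0.23235  0.44463        TRUE
#>           mu_beta[time]  0.00298 -0.00555  0.01071       FALSE
#>  mu_beta[precip_summer]  0.29405  0.13544  0.46569        TRUE
#>    mu_beta[precip_fall]  0.31739  0.08855  0.56560        TRUE
#>  mu_beta[precip_winter]  0.41597  0.20056  0.58430        TRUE
#>  mu_beta[precip_spring]  0.29101  0.15497  0.39333        TRUE
#>    mu_beta[tmax_summer] -0.03388 -0.05501 -0.01258        TRUE
#>      mu_beta[tmax_fall] -0.01841 -0.03973  0.01120       FALSE
#>    mu_beta[tmax_winter] -0.01931 -0.03523 -0.00139        TRUE
#>    mu_beta[tmax_spring] -0.03089 -0.06322  0.00799       FALSE

deriveOverPosterior(fit, sim$panel)
#> DerivedSummary over 400 posterior draws
#>   effective range (intercept): 671 km (95% CI 229-1205)
#>   effective range (coefficients): 497 km (95% CI 238-872)
#>   variance proportions: 12 strata x 11 components
```

The coefficient medians land near the generative truth (lag 0.259, winter
precipitation 0.372, ...), the precipitation effects are positive and the
temperature effects negative, and the intervals for the weak temperature
effects straddle zero — the pattern the model is built to quantify. At this
deliberately short chain length `convergenceGate(splitRhat(fit))` reports a
failure driven by the prior-dominated among-predictor correlation
components (the slowest-mixing block; see the vignette's identifiability
note); the global coefficients above are stable well before `rho` settles.

A command-line pipeline (`simulate`, `build-design`, `fit`, `derive`,
`report`) over CSV/JSON files is available via `runCLI()` or the installed
`exec/pondsvc` script; `fit` exits nonzero when the convergence gate fails.

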