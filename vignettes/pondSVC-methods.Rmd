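---
title: "Spatially varying coefficient models for spring pond abundance: methods and design"
author: "pondSVC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pondSVC methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

pondSVC fits a hierarchical Bayesian regression of annual spring pond counts
observed on a stratified aerial survey of the Prairie Pothole and Great
Plains wetland regions. Pond totals are strictly positive, right-skewed and
heteroscedastic among strata, so the observation layer is lognormal:

$$\mathrm{Pond}_{s,t} \sim \mathrm{LN}(\mu_{s,t}, \tau_s),$$

with a stratum-specific log-scale standard deviation $\tau_s$. The expected
log abundance combines an offset for stratum area (so the intercept reads as
log density per km²) with a linear predictor whose coefficients vary
spatially:

$$\mu_{s,t} = (\mu_0 + w_{0,s}) +
  \sum_p (\mu_{\beta,p} + w_{s,p})\,x_{s,t,p} + \log(\mathrm{area}_s).$$

The predictors, in canonical order, are: the log of the previous year's pond
total (a "holdover" of water conditions), a linear time trend capturing
change not attributable to climate (drainage, restoration), and the log total
precipitation and mean daily-maximum temperature of the four seasons
preceding the late-May survey (summer, fall, winter, spring). Each
coefficient is a global mean plus a spatially correlated stratum-level
deviation — the spatially varying coefficient (SVC) construction — so that,
for example, winter precipitation may drive the eastern strata while fall
precipitation drives the west.

The intercept deviations follow their own Gaussian process,
$w_0 \sim \mathrm{MVN}(0, \sigma_{\beta 0}^2 K_0(\phi_0))$: mean pond density
reflects glacial geomorphology and is allowed a different spatial dependence
than the climate responses. The coefficient deviations share a single
*separable* matrix-normal prior,

$$W \sim \mathrm{MN}(0,\ K_B(\phi_B),\ T), \qquad
  T = \mathrm{diag}(\sigma_\beta)\,\rho\,\mathrm{diag}(\sigma_\beta),$$

equivalent to $\mathrm{vec}(W) \sim \mathrm{MVN}(0, K_B \otimes T)$. The
rows (strata) share one isotropic Gaussian correlation kernel
$K(d) = e^{-\phi^2 d^2}$ and the columns (predictors) share a covariance
split into per-predictor scales $\sigma_\beta$ and a correlation matrix
$\rho$. Separability is what keeps a 10-predictor SVC tractable; a fully
nonseparable model (one kernel per predictor) multiplies the cost without a
matching gain at 24 strata. The Kronecker scale indeterminacy ($cK \otimes
T/c$) is resolved by constraining $K$ to be a correlation matrix, with all
scale carried by $T$.

## Priors

* $\mu_0, \mu_\beta$: Normal(0, sd 10). The intercept receives the same
  prior as the coefficient means; it is one of the Gaussian layers the
  sampler integrates out, so the choice is immaterial beyond being diffuse.
* $\sigma_\beta$, $\sigma_{\beta 0}$, $\tau_s$: Gamma(shape 1.2, rate 0.2)
  (mean 6, sd ≈ 5.48) on the standard-deviation scale.
* $\rho$: LKJ with shape $\eta = 1$, i.e. the uniform density over valid
  correlation matrices. We implement the exact normalized density (checked
  against the elliptope volume for small dimensions) and, in the sampler,
  exploit that $\eta = 1$ is flat with respect to Lebesgue measure on the
  off-diagonals: a positive-definiteness rejection is the entire prior.
* $\phi_0, \phi_B$: Uniform on bounds derived from the geometry, spanning a
  kernel correlation of 0.90 at the largest inter-stratum distance down to
  0.01 at the smallest: $\phi \in
  [\sqrt{-\ln 0.90}/d_{\max},\ \sqrt{-\ln 0.01}/d_{\min}]$. These bounds are
  recomputed from whatever geometry is supplied, so the support always
  covers spatially meaningful ranges.

Distances are Euclidean on planar km coordinates. At the few-hundred-km
scale of the survey a planar approximation is adequate, and it keeps the
geometry fully testable; the package never computes great-circle distances.

# Posterior computation

All Gaussian layers of the model — the global means, the intercept field and
the coefficient field — enter the log-scale likelihood linearly with
Gaussian noise. `runMCMC()` therefore uses a *partially collapsed* sampler
rather than a joint gradient sampler:

1. **Marginal Metropolis.** The Gaussian layer is integrated out
   analytically, leaving a dense $n \times n$ marginal covariance
   ($n$ = strata × modeled years) whose log-density costs one Cholesky
   factorization (evaluated in compiled code). Adaptive random-walk
   Metropolis blocks update the field scales $(\sigma_{\beta 0},
   \sigma_\beta)$, the correlation $\rho$ and the decays $(\phi_0, \phi_B)$
   against this marginal likelihood — log scale for standard deviations,
   logit scale between the uniform bounds for the decays, raw off-diagonals
   with a positive-definiteness rejection for $\rho$. Proposal scales and
   covariances adapt during warmup only.
2. **Exact conditional draw.** Given the hyperparameters, the stacked
   Gaussian layer $u = (\mu_0, \mu_\beta, w_0, \mathrm{vec}\,W)$ is drawn
   exactly from its multivariate-normal conditional, assembled in precision
   form $Q = \Sigma_u^{-1} + A^\top D^{-1} A$ (numerically stable: no
   large-covariance subtraction).
3. **Dispersion slices.** Each $\tau_s$ is updated by a univariate slice
   sampler given the layer's residuals — cheap, tuning-free and effectively
   Gibbs.
4. **Interweaved conditionals.** Slice moves on $\sigma_\beta$, $\rho$,
   $\phi_B$ given the drawn $W$ (through the sufficient statistic
   $W^\top K_B^{-1} W$) and on $\sigma_{\beta 0}$, $\phi_0$ given $w_0$.
   These involve only small matrices and mix quickly where the fields are
   well identified; the marginal Metropolis moves of step 1 carry the
   mixing in the small-scale ("funnel") regime where conditioning on the
   field would stick. The combination of marginal and conditional kernels
   is a valid composition: each step is an exact conditional (or
   collapsed conditional) of the same joint posterior.

Collapsing removes the slow coupling between field scales and field values
that plagues centered spatial hierarchies; because the Gaussian layer is
redrawn exactly every sweep, the global coefficients $\mu_\beta$ have very
low autocorrelation even when some hyperparameters move slowly. The default
chain protocol mirrors the survey analysis (5 chains, 400 warmup, 2000
kept); the test suite and the acceptance script use reduced protocols
(2 × 200 + 200 and 2 × 400 + 2 × 500 sweeps) at reduced problem sizes —
12 strata × 30 years for recovery, 8 × 20 with 3 predictors for
calibration — chosen as the smallest sizes at which the scientific checks
are statistically meaningful.

Convergence is assessed with the split potential scale reduction factor
(each chain halved, classic between/within ratio). The pipeline gate passes
at max split-$\hat R$ ≤ 1.05, warns to 1.1, and fails beyond — the survey
analysis states no threshold, so these conventional values are our choice.
Posterior summaries are pooled-chain medians and central 95% intervals using
linear interpolation of order statistics (R's type 7), recorded in the
output metadata; a coefficient is flagged "significant" when its interval
excludes zero.

Identifiability caveat: with a modest number of strata the field scales and
decay parameters are weakly identified (their posteriors remain close to
their priors), and the among-predictor correlation $\rho$ is essentially
prior-dominated — its components are the slowest-mixing quantities in the
sampler and the usual reason a short run warns on $\hat R$. The global
coefficients, dispersions and derived quantities are robust to this.

# Derived quantities

All derived quantities are computed per posterior draw and then summarized;
none are computed from posterior-median parameters.

* **Effective range**: the distance at which the kernel falls to 0.05,
  $d = \sqrt{-\ln 0.05}/\phi$. (Note the square root: inverting
  $e^{-\phi^2 d^2} = 0.05$ requires it, and the package's form satisfies
  the round trip `gaussianCorrelation(phi, effectiveRange(phi)) == 0.05`
  exactly.)
* **Variance decomposition**: the share of within-stratum variance in log
  pond abundance attributed to predictor $p$,
  $p_{s,p} = B_{s,p}^2 \sigma^2_{s,p} / (\sum_k B_{s,k}^2 \sigma^2_{s,k} +
  \tau_s^2)$, where $B_{s,p}$ is the stratum's total coefficient and
  $\sigma^2_{s,p}$ is the *realized sample variance* of that predictor's
  series in that stratum over the modeled years. The residual share
  $\tau_s^2/(\cdot)$ completes an exact partition of one. The dispersion
  enters once per stratum ($\tau_s$, matching the observation layer), and a
  zero-variance predictor contributes zero rather than NaN.
* **Density and variability**: mean pond density
  $e^{\beta_{0,s} + \tau_s^2/2}$ per km² (the offset makes the stratum
  intercept a log density) and the lognormal coefficient of variation
  $\sqrt{e^{\tau_s^2} - 1}$. The squared form $e^{\tau_s^2} - 1$ is
  available behind a flag for parity with map figures that print it. The
  stratum dispersion $\tau_s$ is the only per-stratum scale in the model
  and is what these transforms use.

# The synthetic-data generator

The generator exists so that every downstream stage is testable without the
proprietary survey and interpolated-climate data. It emulates:

* **Geometry** (`makeGeometry`): a jittered near-square lattice of stratum
  centroids over a 1500 km extent with lognormal areas (mean 17,000 km²,
  log-sd 0.4 — the scale of real survey strata). At the survey's 24 strata
  this yields a mean nearest-neighbour distance of ≈ 250–300 km, matching
  the survey layout.
* **Climate** (`simulateClimate`): per season, log-precipitation and
  temperature fields with deterministic gradients (wetter eastward,
  +0.25 log mm per 1000 km; colder northward, −4 °C per 1000 km) plus
  spatially correlated annual anomalies (Gaussian kernel, default effective
  range ≈ 600 km; log-precip sd 0.30, temperature sd 1.5 °C). Seasonal
  means (180/90/60/110 mm; 24/10/−5/9 °C) are plausible midcontinent
  values. Years are independent: the generator is stationary and does not
  emulate multi-year wet–dry regime cycles, so tests exercise the model's
  statistical structure, not drought persistence.
* **Parameters** (`drawParameters`): hyperparameters are *fixed* at
  configured truth values rather than drawn from the diffuse
  Gamma(1.2, 0.2) hyperpriors, so recovery experiments have a defined
  target; the fields $w_0$ and $W$ are then drawn from their exact
  Gaussian/matrix-normal laws. Default truth values sit at the published
  posterior medians of the survey analysis (lag 0.259 with field scale
  0.144, winter precipitation 0.372, spring temperature −0.039, intercept
  field scale 7.39, decay parameters giving 688 and 644 km effective
  ranges), so synthetic panels exercise the model in its reported regime.
  Values the analysis does not report are chosen once: stratum dispersions
  $\tau_s \sim U(0.10, 0.30)$ (10–30% year-to-year residual variation,
  typical of visibility-corrected pond series), identity $\rho$ (no
  among-predictor correlation was detected), and a global intercept
  $\mu_0 = -7.4$ that balances the lag autoregression and the mean climate
  forcing so the stationary state is of order one pond per km².
* **Panel** (`simulatePonds`): sequential simulation of the observation
  model, building each year's design row (lag of log counts, time, four
  log-precipitation totals, four temperatures), evaluating the linear
  predictor and drawing the count lognormally. The first year seeds the lag
  and is excluded from the likelihood — the same convention the fitting
  code uses. A total lag coefficient of magnitude ≥ 1 in any stratum is
  flagged as non-stationary with a warning, not an error.

# Covariate construction

`seasonalAggregate()` maps monthly climate onto the four seasons preceding
a late-May survey in year $t$: summer = Jun–Aug and fall = Sep–Nov of
$t-1$; winter = Dec of $t-1$ plus Jan–Feb of $t$; spring = Mar–May of $t$.
Spring of the survey year itself is included in full (temperature effects
are expected strongest in the spring immediately preceding the count); the
window is not truncated at the survey date. Precipitation is summed to a
seasonal total and logged *after* summation; temperature is an unweighted
three-month mean. Zero or negative pond counts or seasonal precipitation
totals are domain errors — at stratum scale a 0 mm seasonal total indicates
upstream data failure, and silently adding offsets would bias the log
transforms.

`buildDesign()` assembles the canonical 11-column design (intercept plus 10
predictors). Covariates are deliberately *not* standardized: coefficients
are reported on the log-precipitation and raw-°C scales, and the time trend
is coded as survey year minus first year, which keeps reported magnitudes
(a few 0.001 per year) directly comparable to the survey analysis.

# Validation strategy

The test suite checks, among others:

* the matrix-normal density against a vectorize-and-Kronecker multivariate
  normal oracle (100 random instances, tolerance 1e−8);
* the full joint log-posterior against a monolithic single-MVN
  implementation on a small instance;
* the marginal likelihood against a dense brute-force covariance
  construction, and the exact factorization
  $p(y\,|\,\theta)\,p(u\,|\,y,\theta) = p(y\,|\,u)\,p(u\,|\,\theta)$;
* prior recovery under a masked likelihood (Gamma moments, uniform decay
  bounds respected exactly);
* parameter recovery: on twenty 12 × 30 panels at the default truth, the
  95% intervals for each global coefficient must cover truth in at least
  16/20 replicates with no systematic sign error in the posterior medians;
* simulation-based calibration at 8 strata × 20 years × 3 predictors
  (time, winter precipitation, spring temperature — no lag column). The
  calibration prior is a narrowed, self-consistent configuration
  (Normal(0, 0.5) means, Gamma(2, 8) scales) used both to draw truths and
  to fit: truths drawn from the diffuse analysis priors routinely produce
  explosive lag dynamics and astronomically scaled panels, which tests
  floating-point limits rather than sampler calibration. Calibration is a
  property of the prior–likelihood–sampler triple, so any self-consistent
  prior is a valid probe.
* exact identities for the derived quantities (variance partition to
  1e−12, kernel round trips at machine precision) and the qualitative
  contrast that lag-dominant strata show larger lag variance shares than
  climate-dominant strata.

What passing these tests does *not* show: the generator's stationary
climate and exact lognormal noise mean that robustness to regime cycling,
outliers, missing cells or visibility-correction error in real survey data
is untested; and at 12–24 strata the spatial hyperparameters are only
weakly informed, so recovery statements concern the global coefficients,
dispersions and derived transforms, not $\rho$ or the decay parameters
individually.

# Numerical choices

* Cholesky factorizations of kernel matrices retry with diagonal jitter
  escalating 1e−10 → 1e−6 (relative to the mean diagonal) and fail with an
  eigenvalue report beyond that; Gaussian kernels are notoriously
  ill-conditioned at small decay values.
* The conditional of the Gaussian layer is formed in precision space to
  avoid the catastrophic cancellation of the covariance-form Schur
  complement.
* Zero field scales ($\sigma = 0$) are honored exactly: the corresponding
  blocks leave both the marginal covariance and the conditional, so the
  model collapses cleanly to an ordinary lognormal regression — used by the
  conjugate-oracle tests.
* All randomness flows from the user seed through R's RNG (including the
  compiled path, which performs no random draws); identical seed, settings
  and platform give bit-identical output, and every pipeline stage writes a
  manifest with its seed and a settings hash.
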