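---
title: "Bayesian interrupted time series for psychological distress: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian interrupted time series for psychological distress: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

`itsbayes` implements a quasi-experimental interrupted time series (ITS)
analysis of psychological distress in a UK-style household panel, comparing
minoritised ethnic groups (Black African, Black Caribbean, Indian, Pakistani,
Bangladeshi) with a White reference group across three exposure periods
defined by immigration-policy events: before the Immigration Act 2014
(Aug 1, 2009 to May 13, 2014), after the Act and before the Windrush-scandal
media coverage (May 14, 2014 to Nov 27, 2017), and after media coverage began
and before the first COVID-19 lockdown (Nov 28, 2017 to Mar 23, 2020).
Ethnicity acts as a proxy for exposure to the policy.  The outcome is the
12-item General Health Questionnaire (GHQ-12), Likert-scored 0--3 per item
and summed to a continuous 0--36 distress scale.

Because the panel microdata that motivate this design are licence
restricted, the package pairs the analysis pipeline with a synthetic cohort
generator whose ground truth is known, so every stage — scoring, eligibility
filtering, inverse-probability-of-response weighting, chained-equations
imputation with mode pooling, and the Bayesian ITS model — is testable end
to end.

## The model

For person $i$'s interview at date $t_{ij}$, with ethnic group $g(i)$,
exposure period $p(i,j) \in \{1,2,3\}$, calendar time $c_{ij}$ (years since
Aug 1, 2009) and time since the start of the current period $s_{ij}$
(years, 365.25-day year), the GHQ-12 total $y_{ij}$ is modelled as

$$
y_{ij} \sim \mathcal N\!\left(\mu_{ij},\ \sigma^2 / w_{ij}\right),
$$

$$
\mu_{ij} = \alpha + \beta_{g(i)} + \gamma_p + \delta\, c_{ij}
  + \eta_p\, s_{ij}
  + \underbrace{\theta_{g,p}}_{\text{level contrast}}
  + \underbrace{\lambda_{g,p}\, s_{ij}}_{\text{slope contrast}}
  + \mathbf{x}_{ij}'\boldsymbol\kappa
  + u_{\mathrm{year}(t_{ij})} + v_{\mathrm{area}(i)},
$$

with treatment coding against the references (White; period 1): $\gamma_p$
and $\eta_p$ exist for periods 2 and 3, and the ethnicity-by-period level
contrasts $\theta_{g,p}$ (the reported *mean differences*, in GHQ-12 points)
and per-year slope contrasts $\lambda_{g,p}$ exist for each non-reference
group and each of periods 2 and 3.  $\mathbf{x}_{ij}$ collects the
confounders (sex, age, urbanicity, relationship status, number of children,
education, health impairment, housing, deprivation, employment, UK-born,
household income).  $u$ and $v$ are iid Gaussian random effects over
interview calendar years and local authority areas, absorbing residual
temporal and spatial confounding.

Two coding decisions deserve note:

* **Period contrasts are "vs-baseline" by default**: the period-3 indicator
  contrasts period 1, so $\theta_{g,3}$ is the cumulative difference since
  the pre-Act era.  This matches results narrated as a *further* increase in
  period 3 over the period-2 value.  A `"sequential"` option codes period 3
  against period 2 instead.
* **Slopes are per-period by default**: `time_since_period` enters as two
  columns (one per post-interruption period), each interacted with
  ethnicity, because the reported tables carry *distinct* period-2 and
  period-3 slope contrasts per group.  A `"common"` option uses a single
  time-since-interruption slope (five ethnicity-interaction columns), the
  minimal alternative reading.  In period 1, time since the period start
  equals calendar time exactly, so a separate period-1 slope would be
  collinear with the secular trend and is not included.

Priors are weakly informative on the GHQ-point scale:
$\mathcal N(0, 10^2)$ on every fixed-effect coefficient (configurable;
`Inf` gives a flat prior) and half-$\mathcal N(0, 5^2)$ on the residual and
random-effect SDs.  GHQ-12 scores live on a 0--36 scale, so coefficient
magnitudes above a few points are already extreme; scale-10 priors stabilise
the fit without constraining plausible effects.

### Weights

Longitudinal non-response weights are built from empirical cell proportions:
within each sampling stratum and exposure period, the response probability
is the share of the included cohort's persons in that stratum with at least
one eligible interview in the period, and the weight is its reciprocal.  No
model smoothing and no trimming are applied — cells are coarse, and an
extreme weight indicates a configuration problem better surfaced than
hidden.  The weights enter the Gaussian likelihood as per-row log-likelihood
multipliers (a pseudo-likelihood, the standard way survey weights meet a
Bayesian model; the resulting posterior spread is approximate under
informative weighting).  Weights are normalised to mean 1 inside the fitter,
so a global rescaling of all weights cancels exactly and uniform response
reproduces the unweighted fit.

### Inference engine

The posterior is sampled by a Gaussian-conjugate Gibbs sampler written in
C++ (RcppArmadillo).  The coefficient block and each random-effect block
have exact multivariate/univariate Gaussian full conditionals; the three
standard deviations are updated by univariate slice sampling on the log
scale (stepping-out with shrinkage), which handles the half-Normal priors
without conjugacy tricks.  Convergence is monitored with split-chain
$\widehat R$ and effective sample sizes per parameter; a run whose maximum
split-$\widehat R$ exceeds 1.05 is flagged (`converged = FALSE`) with a
warning, never returned silently.

Coefficient posterior *means* are Rao-Blackwellised — averages of the exact
conditional means $E[\beta \mid \sigma, u, v, y]$ across iterations — which
removes almost all Monte Carlo noise from point estimates; in the flat-prior,
unit-weight, no-random-effects case the conditional mean does not depend on
the conditioning draws at all, so the reported posterior mean equals the
weighted-least-squares solution to numerical precision.  Interval summaries
use the empirical quantiles of the draws.

The default sampler settings (4 chains, 2000 iterations, 1000 warmup) give
split-$\widehat R$ below 1.02 on cohorts of a few thousand interviews; the
variance-component SDs are the slowest movers.  Rows are sorted by person id
and interview date before any random number is drawn, so row order never
affects results.

Degenerate inputs are handled explicitly: residual SDs are bounded below at
$10^{-6}$ (so noiseless data pin the coefficients at the least-squares
solution instead of underflowing), constant design columns are dropped with
a warning, and remaining rank deficiency is an error.

### Imputation and pooling

Missing categorical covariates are filled by chained equations: missing
cells are initialised from observed marginals, then each incomplete variable
is regressed (multinomial logistic via `nnet::multinom`, ridge-stabilised
with a small weight decay for sparse categories) on the other covariates
plus sex and ethnicity, and missing cells are redrawn from the fitted
conditional; ten sweeps and five imputations by default.  The completed
datasets are then pooled *before* analysis by taking the per-cell mode
across imputations (ties to the lowest category code), and all analyses run
on the single pooled dataset.  This mode-pooling rule deliberately departs
from Rubin's rules — it reproduces the emulated analysis exactly, and
Rubin-style variance combination is an explicit non-goal.  The outcome, sex
and year of birth are never imputed; persons missing sex or birth year are
excluded instead.

## The synthetic cohort generator

The generator emulates the published cohort's structure with every
parameter planted and recorded:

* **Composition.**  Ethnic proportions (78.9% White, 4.3% Black African,
  3.8% Black Caribbean, 5.4% Indian, 4.8% Pakistani, 2.7% Bangladeshi),
  per-group UK-born fractions and per-group baseline GHQ-12 means and SDs
  follow the published descriptive table.  Other categorical confounders are
  drawn from simple configured multinomials matching the published margins;
  their joint distribution with ethnicity is not modelled (only UK-born
  varies by group), which is a stated non-goal.
* **Waves.**  Eleven 24-month interview windows, the first opening
  Aug 1, 2009, each shifted 12 months, so adjacent windows overlap and one
  wave can straddle two exposure periods; each person draws one uniform
  interview date per wave.  Dates after the study end are emitted and left
  to the eligibility filters, as are under-16 interviews (ages 15--89 at
  study start).
* **Non-response.**  A candidate interview is kept with a stratum-by-period
  response probability (default: period-level means 0.60/0.50/0.45 with a
  linear stratum gradient of about 0.03), emulating stratified attrition
  that deepens over time.  About 5% of interviews omit part of the GHQ-12
  questionnaire, exercising the outcome-completeness filter.
* **Outcome.**  The latent mean follows exactly the fitted model's linear
  predictor — group baseline, secular trend, planted group-by-period level
  and slope effects (defaults: the published point estimates; zero for
  White), iid year and area effects (SD 0.4 each) — plus Gaussian noise.
  The observed total is rounded, clamped to [0, 36] and decomposed into 12
  items greedily (fill to 3 in index order); only the total enters the
  analysis, so the item structure exists to exercise the scorer.  Clamping
  counts are recorded in the truth map.
* **Calibration under clamping.**  The latent baseline per group is solved
  (closed-form clamped-normal mean) so the *post-clamping* period-1
  marginal mean equals the configured target; empirical group means
  therefore converge to the configured values as the cohort grows.  The
  default secular trend is 0 and default covariate effects on the outcome
  are 0, keeping the period-1 group means exactly at their calibrated
  values (both are configurable).
* **Missingness.**  Covariate cells are masked independently
  (per-cell Bernoulli); the default rate 0.003 makes roughly 87% of
  included persons fully observed, matching the published person-level
  completeness.  Two published figures coexist here — person-level
  completeness of 87% and a quoted "~13%" item-level reading — and the
  person-level figure is the calibrated one.
* **Residual SDs.**  Per-group residual SDs are derived from the configured
  total SDs by removing the year and area components; supplying a scalar
  `sigma_resid` forces a common value.

What the generator does **not** emulate: household clustering, the panel's
official design weights, realistic confounder joint distributions, item-level
response styles, and COVID-era interviews.  Passing tests therefore
demonstrate the pipeline's correctness under the stated data-generating
process, not robustness to every feature of real panel data.

## Simulation studies the package ships with

Problem sizes were chosen to give informative Monte Carlo precision at
desk scale; the methods are identical at any size.

* **Coverage.**  200 cohorts of 2000 persons are generated under the
  default calibration with one change: a common outcome SD of 5.4 across
  groups, because the coverage property of a correctly specified model is
  only defined when the fitted (homoscedastic) model is the data-generating
  one.  Non-response in the generator depends only on stratum and period —
  never the outcome — so the unweighted model is correctly specified and is
  the one fitted; pseudo-likelihood weighting deliberately trades exact
  posterior calibration for design consistency and is exercised separately.
  Complete-case rows are used since masking is completely at random.  The
  share of replicates whose central 95% credible interval for the
  Black-Caribbean-by-period-2 coefficient contains the planted value is
  compared with 95% within binomial Monte Carlo error.  A companion
  diagnostic (the z-scores of posterior means against the truth) sits near
  mean 0, SD 1 when the sampler and model are right.
* **Recovery.**  100 cohorts of 5000 persons with a single planted level
  effect of +1.0 GHQ points (Black Caribbean, period 2).  The recovery
  experiment uses the standard design for bias assessment: balanced ethnic
  proportions, complete response, and a mid-scale baseline (15) at which
  boundary clamping is negligible, so the replicate mean isolates estimator
  bias from design artefacts.  The absolute bias bound is 0.1 GHQ points.
* **Noiseless recovery.**  With all variance components zero, an integer
  baseline and a single planted effect, the pipeline must return the planted
  value to 1e-3 — this exercises the degenerate-input path end to end.
* **Calibration.**  A default cohort of 50 000 persons reproduces the White
  group's period-1 mean of 11.1 within Monte Carlo error.  Note that the raw
  period-1 mean averages over only about six realised year-effect draws
  (SD 0.4 each), so its replicate-to-replicate SD is ~0.18 however large the
  cohort; the calibration check therefore nets out the realised year and
  area effects recorded in the truth map, leaving observation-level Monte
  Carlo error (~0.02 at this size).

## Numerical choices and edge cases

* Year length 365.25 days for all time covariates; the interruption dates
  are inclusive interval endpoints exactly as printed.
* Age is interview year minus birth year (panels typically provide year of
  birth only).
* Eligibility filters run in a fixed order (out-of-range dates, under-16,
  incomplete outcome, missing sex/birth year, out-of-scope ethnicity) so the
  exclusion log is deterministic and comparable across runs; the filters are
  idempotent.
* A person interviewed twice within one period keeps both rows by default
  (`first_per_period = TRUE` keeps the earliest): the emulated analysis is
  silent here, and discarding interviews loses information.
* The income stratifier dichotomises the ordinal household-income code at
  its cohort median, with the exact-median value in the lower stratum
  (determinism over symmetry).
* Stratified analyses refit the main model on row subsets of the main run's
  pooled, weighted dataset: the model specification and the weights are
  those of the main analysis, only the rows change.
* The weight-table reading of "inverse probability of responses within each
  exposure period ... for each sampling stratum" is the empirical
  cell-proportion one; a person-level modelled response probability is a
  plausible alternative reading that is intentionally not implemented.

## Known limitations

* The inference contract is the posterior of the stated model, not a
  reproduction of any particular approximation engine; deterministic
  engines would give slightly different interval endpoints.
* Pseudo-likelihood weighting does not propagate design-based uncertainty;
  with strongly informative weights the intervals are approximations.
* Mode pooling before analysis (as emulated) understates imputation
  uncertainty relative to Rubin's rules by construction.
* The year and area random effects are exchangeable (iid); random-walk
  temporal or adjacency-based spatial structures are out of scope.
* Published headline estimates from the original licence-restricted panel
  are not reproducible from synthetic data; the package's claims are about
  the method, exercised under a known truth.
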