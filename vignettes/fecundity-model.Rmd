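---
title: "A hierarchical zero-inflated Poisson model of annual fecundity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical zero-inflated Poisson model of annual fecundity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipfec)
```

## The scientific problem

Fecundity — the number of juveniles a breeding pair raises to (near)
independence in one season — is the vital rate that most analyses of
territorial, cooperatively breeding birds turn on.  Its data have an
awkward shape: in long-term monitoring panels a large majority of
pair-years produce *zero* young, because whole-brood failure (nest
predation, abandonment) and post-fledging mortality are distinct
processes.  A single Poisson or negative-binomial regression conflates
them.  `zipfec` fits the two processes separately while sharing the
panel's grouping structure.

## The model

One record is a pair-year: juvenile count $C_{ypt}$ in year $y$,
population $p$, territory $t$, with covariates.  The two submodels are

$$S_{ypt} \sim \mathrm{Bernoulli}(p_{ypt}), \qquad
  \mathrm{logit}(p_{ypt}) = \mathbf{x}_s'\boldsymbol\beta_s +
  \mathrm{Year}^{(s)}_y,$$

$$C_{ypt} \sim \mathrm{Poisson}(S_{ypt}\,\lambda_{ypt}), \qquad
  \log(\lambda_{ypt}) = \mathbf{x}_c'\boldsymbol\beta_c +
  \mathrm{Year}^{(c)}_y + \mathrm{Population}_p + \mathrm{Territory}_t,$$

with independent zero-mean normal random effects,
$\mathrm{Year}^{(s)}_y \sim N(0, \sigma^2_{\mathrm{yr},s})$ and so on.
$S$ is the *brood success* indicator; on observed data it is defined as
$S = \mathbf{1}(C > 0)$, so the Bernoulli part is the zero-inflation
process and the Poisson part models counts among successful pairs.

Two modelling facts deserve emphasis:

* **The Poisson factor is not zero-truncated.**  With $S$ observed, the
  likelihood contribution of a successful pair is
  $\mathrm{Poisson}(C\,|\,\lambda)$ evaluated as-is, which leaves
  $e^{-\lambda}$ of probability mass on $C = 0$ even though such rows
  cannot arise when $S$ is derived from $C$.  We implement this form
  deliberately — it is the factorization under which the reference
  posterior estimates are defined — and we expose the tension through
  the simulator's three generative modes (below).  The marginal
  zero-inflated Poisson pmf
  $P(C = c) = (1-p)\mathbf{1}(c=0) + p\,\mathrm{Poisson}(c|\lambda)$ is
  provided as an independent oracle; summing the factorized likelihood
  over the latent $S$ at $C=0$ recovers it exactly, and the test suite
  checks both normalizations by brute-force enumeration.
* **Success and count year effects are separate vectors** with separate
  SDs and no correlation parameter.  Their empirical correlation is a
  posterior *diagnostic* (below), not a model parameter.

### Covariates and coding

The success design matrix carries (in order): intercept, strong, weak,
nonbreeders present, population density, male experience, female
experience, territory size, rainfall.  The count design matrix carries:
intercept, strong, weak, nonbreeders present, territory size, rainfall,
proportion of strong territories in the population, supplemental
feeding, population density.  Sink is the habitat reference state, so
habitat enters as two dummies — strong $(1,0)$, weak $(0,1)$, sink
$(0,0)$.  Rainfall (cumulative December–February, mm) varies at the year
level only and is broadcast to rows; density and proportion-strong vary
at the population-year level; supplemental feeding is a per-population
flag.

Continuous and count-valued covariates (territory size, density,
proportion strong, rainfall) are centred and divided by **two** standard
deviations, giving them SD 0.5 and making their coefficients directly
comparable with those of the untouched 0/1 indicators.  Moments are
computed from all non-missing values of the rows being analysed and are
stored in a scaling report used for back-transformation and prediction;
subsetting a table therefore changes the standardized values of the
remaining rows, by design.

### Missing breeder experience

Experience is coded 1 (bred before), 0 (novice) or missing.  Rather
than dropping rows, the sampler treats each missing cell as a latent
Bernoulli variable with a fitted population-level prevalence (one per
sex, Beta(1,1) prior, conjugate updates); the cells are imputed by exact
Gibbs draws inside the MCMC, so their uncertainty propagates into every
posterior.  Functions that need a pointwise complete design outside the
sampler (`linear_predictors()`, `joint_log_likelihood()`) require
explicit completion via `complete_design()`.

### Priors

Normal(0, 10) on every coefficient (logit/log scale) and half-normal —
the right half of $N(0, 2.24)$, density $2\varphi(x; 0, 2.24)$ on
$x \ge 0$ — on each random-effect SD.  The half-normal is similar in
shape to a half-Cauchy near zero but short-tailed, which matters because
the count submodel exponentiates its random effects; heavy-tailed SD
priors slow convergence badly there.  A prior-only run of the sampler
(`fit_zipfec(..., prior_only = TRUE)`) reproduces these distributions,
which the suite verifies with a Kolmogorov–Smirnov test.

## Inference

`fit_zipfec()` runs an adaptive Metropolis-within-Gibbs sampler
(compiled, single-threaded) with the protocol: 3 chains from dispersed
random starts ($\beta \sim N(0, 0.5)$, $\sigma \sim |N(0, 0.5)|$), a
burn-in discarded in full, then sampling in blocks until the
split-chain Gelman–Rubin statistic of every monitored parameter (all 18
coefficients and 4 SDs) is below 1.01, with no thinning.  If the
per-chain draw cap is hit first, the fit is returned flagged
unconverged, with a warning.  Random-effect vectors are reported but do
not gate convergence: individual effects mix more slowly than the
structural parameters, and the gate follows the monitored set a
practitioner actually reports.

The update sweep combines:

* scalar random-walk Metropolis on each coefficient, with
  delta-likelihood evaluation against cached linear predictors;
* blocked random-effect updates — all groups of a block proposed
  jointly and accepted per group, exact because groups touch disjoint
  rows;
* slice sampling for each SD's closed-form conditional (no tuning, and
  it preserves the half-normal prior exactly, including near the
  $\sigma = 0$ boundary);
* ancillary likelihood-invariant moves: intercept ↔ year/population/
  territory effect shifts, rainfall-slope ↔ year-effect and
  supplemental-food ↔ population-effect exchanges.  Year- and
  population-level covariates are nearly confounded with the
  corresponding random effects, and plain random-walk updates stall on
  the induced posterior ridges; these moves traverse them at negligible
  cost.
* non-centred SD rescaling: with $\tilde u = u/\sigma$ held fixed,
  $\sigma$ is proposed on the log scale and $u$ rescaled.  This is the
  standard cure for the funnel that appears when a variance component is
  near zero (the territory SD here), where centred updates mix
  arbitrarily slowly.

Proposal scales adapt toward 44% acceptance during burn-in only, in
batches of 50 iterations with diminishing steps, so post-burn-in draws
come from a fixed, valid transition kernel.  All randomness passes
through R's RNG with per-chain seeds derived from one master seed: the
same seed and data reproduce every draw bit-for-bit.

Convergence is assessed by the split-chain form of the Gelman–Rubin
statistic (each chain halved, guarding against within-chain drift; the
classic form is the cross-check in the tests) and effective sample
sizes from `coda::effectiveSize()`.

## Posterior diagnostics

**Freeman–Tukey posterior predictive check.**  Per retained draw, the
discrepancy $\sum_i (\sqrt{C_i} - \sqrt{E_i})^2$ with
$E_i = p_i \lambda_i$ (the marginal expected count; the model does not
define an "expected count" by itself, and this choice keeps the
observed and replicate discrepancies exchangeable) is compared with the
same statistic on a replicate data set drawn from that draw's
$(p_i, \lambda_i)$ — i.e. conditioning on the realized random effects —
under the exact-likelihood law $S \sim \mathrm{Bern}(p)$,
$C \sim \mathrm{Pois}(S\lambda)$.  The Bayesian p-value is the fraction
of draws where the replicate discrepancy exceeds the observed one;
values near 0 or 1 flag misfit.  Missing-experience cells enter the
replicate predictors at the draw's prevalence (posterior-mean
imputation); with experience effects of order 0.1 on the logit scale
this approximation is far below the check's resolution.

**Runs test on annual effects.**  Repeated good or bad years matter for
population viability, so per posterior draw we count sign changes along
the year-effect sequence and compare with the sign changes of a freshly
drawn Bernoulli(1/2) ±1 sequence of the same length; the p-value is the
frequency that the year effects show *fewer* changes (strict
inequality; ties count zero, and a mid-p variant is available).  Under
an exchangeable null both counts are independent Binomial($Y-1$, 1/2),
which gives the exact calibration target the tests check.  Exact zeros
in a draw (probability zero in theory) inherit the previous element's
sign, a leading zero counts positive — a deterministic tie-break.  All
post-burn-in draws are used.

**Year-effect correlation.**  Per draw, the Pearson correlation across
years between the success and count year-effect vectors; its posterior
mean and 95% interval summarize whether the two processes share their
annual variation.  Draws with a degenerate (constant) vector are
excluded and counted.

## The synthetic panel generator

`sim_config()` + `simulate_panel()` generate territory-year tables with
the structure the analysis assumes.  The default schedule reproduces
the 31-season shape of the motivating monitoring study — 1 population
of 20 territories growing to 14 populations and 234 territories at
peak, contracting to 4 populations of roughly 110 — with annual totals
split evenly across active populations (the per-population breakdown
was never published).  Territories persist between consecutive years
with probability 0.9 by default (no turnover rule is published; the
knob is configurable), and territory size is a persistent property of
the territory.

Default true parameters are the reference posterior means
(`default_params()`); `zeroed_params()` gives the null model.
Covariate distributions are configurable placeholders chosen once to be
realistic for fire-maintained scrub landscapes: habitat states
(strong, weak, sink) categorical at (0.2, 0.3, 0.5) — sink-dominated,
as restoration-era landscapes are; rainfall lognormal with median
250 mm; territory sizes lognormal around 10 ha; pair density
Beta(8, 3); nonbreeders present in 60% of pair-years; experienced
breeders at 75% with 10% of experience values missing; 30% of
populations supplementally fed.  Under these defaults and the full
default schedule the marginal zero-count fraction is ≈76–77%,
matching the ~3/4 zero fraction characteristic of the motivating data.
The generator emulates panel structure, not ecology: no habitat-state
succession, dispersal, survival or fire dynamics — so passing recovery
tests demonstrates correct inference *given the model*, not realism of
the covariate process.

Three generative modes make the likelihood/data tension explicit:

* `likelihood-exact` (default): $S \sim \mathrm{Bern}(p)$,
  $C \sim \mathrm{Pois}(S\lambda)$, both recorded exactly as drawn —
  success-without-young rows occur with probability $p e^{-\lambda}$.
  This is the fitted likelihood read as a generative law, so
  parameter-recovery tests are unbiased (generator = model).
* `hurdle`: counts for successful pairs are zero-truncated Poisson;
  $(S{=}1, C{=}0)$ rows never occur.  This is the data-consistent
  reading; fitting the exact-likelihood model to it quantifies the
  inconsistency.
* `zip-marginal`: $C$ from the marginal ZIP pmf with
  $S := \mathbf{1}(C>0)$, the latent-success reading.

## Numerical choices and edge cases

* Zero-SD continuous covariates, unknown habitat labels, negative
  counts, inconsistent success/count pairs, and rainfall varying within
  a year are validation *errors*, reported with row and column.
* $\mathrm{Poisson}(0\,|\,0) = 1$: unsuccessful rows contribute only
  their Bernoulli factor; a positive count with $S = 0$ is an error.
* `log1pexp` uses the standard threshold decomposition, so logit
  likelihoods are stable for $|\eta|$ into the hundreds; non-finite
  proposal deltas are rejected rather than propagated.
* HPD intervals use the shortest-interval-over-sorted-draws method.
* Equal-tailed 95% intervals summarize coefficients (the convention of
  the reference summary table); HPD is used for the annual-effect
  figures' 90/95% intervals.
* Fecundity is defined as $p\lambda$, the marginal expected
  juveniles/pair-year; profile predictions set random effects to zero
  (population-average) and hold unspecified continuous covariates at
  their data means — the reference-profile convention (whether the
  original figures marginalized over observed covariate values instead
  is unstated; the reference-profile choice is documented and
  overridable via explicit profile columns).

## Problem sizes used for validation

The suite validates at desk scale, chosen so the full run stays in the
tens of minutes: recovery and calibration use 20 replicate panels of 10
years × 3 populations × ~20 territories (~600 pair-years) fitted with 3
chains × (2,000 burn-in + up to 6,000 draws); the acceptance script
fits one quarter-scale 31-year panel (~900 pair-years).  At these sizes
the 95% intervals of well-identified effects (habitat, nonbreeders)
are sharp, while population-level effects with 3 populations
(supplemental food, density) are prior-dominated — their coverage is
trivially high and their recovery should not be over-read.  Full-scale
analyses (≈3,500 pair-years, chains run to millions of iterations) use
the same code path with larger `burnin`/`max_draws`.

## Known limitations

* The sampler is a random-walk method; for much larger panels a
  gradient-based engine would reach a given effective sample size
  faster.  The posterior, not the algorithm, is the contract — the
  suite cross-checks posterior means against an independent Gibbs
  engine (JAGS) on a shared panel.
* The quadratic-nonbreeder effect reported as poorly estimated in the
  motivating study is out of scope, as are habitat-state dynamics,
  density computation from maps, and rainfall retrieval (rainfall is a
  supplied column).
* With few populations the supplemental-food coefficient and the
  population SD are only weakly identified; this is a property of the
  design, not the sampler, and shows up as wide, prior-shaped
  posteriors.
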