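---
title: "Integrated growth and survival modelling for size-dependent demography"
author: "vbcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated growth and survival modelling for size-dependent demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

For elusive animals with low recapture rates — the motivating case is an
endangered gartersnake surveyed with daily funnel-trap checks each spring —
most individuals are never measured again after first capture.  Estimating
how survival depends on body size then requires a size value for every
individual in every year, almost all of which are unobserved.  `vbcmr`
addresses this by embedding an individual growth model inside a
capture–mark–recapture (CMR) model, so body size is imputed *with
uncertainty* wherever it is missing, and size can act as a covariate of
survival, daily capture probability, and availability for capture.

## The growth model

Growth follows a von Bertalanffy curve parameterized so that the growth
coefficient and the asymptote vary independently:

$$E[L_{i,t}] = a_i - (a_i - L_{i,t-1})\,
  \exp\!\left(-\tfrac{k_{i,t}}{a_i}\,\Delta t\right),$$

with observed lengths normal around this expectation with residual SD
$\sigma_e$ (measurement error plus individual deviation).  The hierarchy
is

$$\log k_{i,t} = \mu_f + \beta_m m_i + \alpha_{\mathrm{sex},s} + \zeta_t +
  \iota_i, \qquad
  a_i = \upsilon_f + \theta_m m_i + \eta_{\mathrm{sex},s},$$

where $m_i$ is a male indicator (latent Bernoulli(0.5) for unknown-sex
individuals), $\alpha$ and $\eta$ are sex-by-site effects, $\zeta_t$ year
effects, and $\iota_i$ individual effects, all mean-zero normal with
estimated SDs.

**Time units.** The kernel takes $\Delta t$ in years; day counts between
captures (which include the inactive season) are divided by 365.25.  With
typical posteriors around $\log k \approx 5.5$ and $a \approx 700$ mm the
exponent $k/a \approx 0.35$ is an annual rate — a per-day reading would
imply biologically impossible growth, which is why the package fixes the
annual convention.  Increments that span several calendar years are
segmented at 1 January boundaries so each year's $\zeta_t$ multiplies
exactly the time spent in that year; because the kernel is exponential in
$\sum_t k_{i,t}\,\Delta t_g / a_i$, this composition has a closed form and
costs nothing.

**Priors** (defaults, overridable in `growth_priors()`):
$\upsilon_f \sim N(750, 200)$ mm, $\theta_m \sim N(0, 200)$ mm,
$\mu_f, \beta_m \sim N(0, 10)$, the log-$k$ effect SDs
$\sim \textrm{Exp(rate 1)}$, and the mm-scale SDs ($\sigma_{a,s}$,
$\sigma_e$) $\sim \textrm{Exp(rate 0.1)}$ (prior mean 10 mm) — weak enough
that snake-scale data dominate.  A single $\sigma_e$ is shared across
years: with at most a few measurements per individual, year-specific
residual SDs are not identifiable.

The individual effect $\iota_i$ is only informed by individuals with at
least two measurements; others simply contribute nothing to its
likelihood, and the hierarchical prior keeps them proper.

## The robust-design survival model

The CMR data have a robust design: widely separated annual *primary
periods*, each containing tens of daily *secondary occasions* across which
the population is assumed closed.  Each individual is, in each primary
period, in one of three states — available for capture, temporarily
unavailable (alive but off-site), or dead/permanently emigrated.  Under
*random emigration*, a survivor's availability does not depend on its
previous state, so both alive states share the transition row
$[\phi\gamma,\ \phi(1-\gamma),\ 1-\phi]$, and death is absorbing.  On the
logit scale:

$$\mathrm{logit}(\phi_{i,t}) = \pi_{\phi,\mathrm{sex},s} + f_\phi(x_{i,t})
  + \xi_t,$$
$$\mathrm{logit}(p_{i,t,j}) = o_{p,\mathrm{sex},s} + \delta_p' W_{t,j}
  + f_p(x_{i,t}) + \omega_{s,t},$$
$$\mathrm{logit}(\gamma_{i,t}) = \varsigma_{\gamma,\mathrm{sex},s} +
  \lambda_\gamma x_{i,t} + \nu_{s,t},$$

with $x_{i,t}$ the standardized latent size, $W$ the standardized survey
covariates (air temperature, relative humidity, day of year, and a binary
24-h precipitation flag), and $\omega_{s,t}$, $\nu_{s,t}$ site-by-year
random effects.  The capture-effect subscript is deliberately site-by-year,
not per-occasion: a per-occasion effect would be confounded with the
Bernoulli noise of daily detections.  The annual effects on growth and
survival, $(\zeta_t, \xi_t)$, are drawn from a bivariate normal with SDs
$(\sigma_{k,t}, \sigma_{\phi,t})$ and correlation $\rho \sim U(-1,1)$, so
good growth years and good survival years can be linked.

**Likelihood.** The model conditions on first capture (CJS conditioning):
an individual is available with probability one in its release primary;
occasions before its first detection contribute nothing, occasions after
it contribute Bernoulli terms.  The latent state sequence is marginalized
by the forward algorithm rather than sampled: within each primary, the
available state emits the product of Bernoulli detection terms, while the
unavailable and dead states emit probability one for an all-zero history
and zero otherwise.  This is exactly the "known-available" device — an
individual that was off-site tells us nothing about $p$ — and
marginalization makes it automatic.  The production implementation is a
C++ pass over individuals (`src/forward.cpp`); a readable R version
(`history_log_likelihood()`) serves as the reference, and both are tested
against brute-force enumeration over all latent-state sequences.

**Latent sizes.** Each individual's size trajectory is propagated
deterministically from its first-capture SVL with the growth kernel,
between survey-window midpoints of consecutive primaries, using the
sex-site growth means and the year effects $\zeta_t$ (no individual
$\iota_i$ in this stage: snakes never remeasured carry no information
about it, and dropping it keeps the latent dimension equal to the number
of unmeasured inputs).  Remeasurements enter the joint likelihood as
$N(\text{latent size}, \sigma_e)$, so the CMR data update the growth
block.  Individuals not measured at first capture get a latent initial
size with a normal prior from their sex's measured mean and SD;
unknown-sex individuals get a latent male indicator shared by the growth
and CMR blocks.

**Stage-1 prior transfer.** The growth model is fitted first to the
(richer) growth data; its posterior enters the joint model as independent
normal approximations — posterior mean and SD for location parameters, the
log scale for SDs — widened by an inflation factor (default 2).  The
widening acknowledges that the stage-1 posterior is itself an estimate and
avoids double-counting the remeasurements that appear in both stages.
`cmr_priors(inflation = )` exposes the factor.

**Intercept priors.** Mean survival, capture, and availability intercepts
get flat Beta(1,1) priors on the probability scale, which on the logit
scale is the standard logistic distribution — that is how `cmr_priors()`
encodes them.  Covariate slopes get $N(0,1)$ on the standardized scale;
random-effect SDs get Exp(1).

## Penalized spline size effects

Size effects on survival and capture probability are low-rank penalized
splines in truncated-power form:

$$f(x) = q\,x + \sum_{g=1}^{G} b_g\,(x - \kappa_g)_+^d,
  \qquad b_g \sim N(0, \sigma_b),$$

with $G = 5$ knots, degree $d = 3$, and knots at the empirical quantiles
$g/(G+1)$ of the observed SVL sample.  Conventions fixed for
reproducibility, where the formulation leaves latitude:

* *Quantile rule*: linear-interpolation quantiles (R type 7).
* *Standardization*: SVL is centered and scaled by the sample mean and SD
  of observed measurements before knot placement and basis evaluation —
  cubes of raw millimetre values would be numerically hostile.  The
  constants are stored in the `spline_spec` so fitted smooths are
  reusable for prediction.
* *Frozen knots*: knots come from observed measurements only, never from
  imputed latent sizes, and are fixed before sampling.
* *Shared shape*: one smooth per response ($\phi$, $p$) shared across
  sexes and sites (intercepts differ); availability gets a linear slope
  $\lambda_\gamma$ only, since a flexible availability-size curve is not
  identifiable without auxiliary data.
* $\sigma_b \sim$ Exp(1) (not stated by the formulation; matches the other
  SD priors and is exposed in `cmr_priors()`).  As $\sigma_b \to 0$ the
  smooth collapses to the straight line $q\,x$ — the shrinkage limit the
  test suite checks by pinning $\sigma_b = 10^{-6}$.

The truncated-power basis is used as printed rather than the radial
$|x-\kappa|^3$ thin-plate variant; with five knots and shrinkage the two
parameterizations describe the same function space up to the penalty.

## Sampling

Both fits use an adaptive Metropolis-within-Gibbs sampler written for this
package: scalar random-walk updates for structural parameters (batch
adaptation toward 44% acceptance), joint random-walk updates for
random-effect and coefficient vectors (toward 23%), multiplicative updates
on the log scale for SDs, vectorized elementwise updates for per-individual
latent quantities (exploiting the likelihood's factorization across
individuals), and Gibbs draws for latent sex indicators.  Likelihood
evaluation is cached by dependency, so e.g. a survival-intercept proposal
re-evaluates only the survival probabilities and the forward pass.  Fits
are exactly reproducible given `seed` and the MCMC configuration, and
`convergence_report()` applies the split-chain potential scale reduction
factor with a 1.05 flag threshold.

Defaults are 4 chains of 5,000 retained draws after 2,000 warm-up
iterations.  The original JAGS-era analysis this design follows ran
millions of iterations; the marginalized likelihood and adaptive proposals
here converge far faster, and the test suite runs reduced budgets (2
chains, 600–900 warm-up, 700–1,200 draws) chosen to keep a full
parameter-recovery study around ten minutes on one core.

## Model checking

* **Growth**: residual sum of squares of observed versus expected lengths,
  compared per posterior draw with the same statistic on lengths
  re-simulated from that draw.
* **Robust design**: Freeman–Tukey discrepancy
  $\sum (\sqrt{y} - \sqrt{E[y]})^2$ on the indicator of recapture per
  individual and primary period, with
  $E[y] = \Pr(\text{available}) \times p^*$, where $p^*$ is the
  probability of at least one detection across the primary's occasions.
  $\Pr(\text{available})$ can be the one-step-ahead filtered probability
  given the detection history (`mode = "conditional"`, the default) or the
  unconditional state distribution from the transition chain
  (`mode = "marginal"`); replicate data are simulated generatively from
  each draw and, in the conditional mode, filtered the same way.
* Bayesian p-values count replicate discrepancies greater than *or equal
  to* the observed one — ties count toward the event.  Values near 0.5
  indicate adequate fit; both checks are calibrated on model-true
  synthetic data in the test suite.

## The synthetic-data generator

`simulate_study()` emulates the motivating study design: two CMR sites
with staggered spans (defaults: one site with 14 annual primary periods,
one with 4), ~52 daily occasions in a spring window, staggered recruitment
(30% neonates, the rest entering at uniform ages up to 8), sparse
recaptures, ~1% unmeasured captures and ~3% unknown sex.  Demographic
truth defaults to typical posterior values for the motivating system:
female asymptote 737 mm with a −187 mm male effect, log growth coefficient
5.55 (+0.34 male), annual survival 0.52–0.68, availability 0.33–0.65, and
daily capture probability 0.010–0.020 by sex and site, with annual effect
SDs 1.19 (survival), 0.65 (capture), 1.36 (availability) and correlation
0.012 between growth and survival year effects.  Where the emulated study
reports no value, defaults were chosen once on biological grounds: the
availability–size slope is 0.5 logits per 100 mm (positive, matching the
reported direction), the size–survival truth curve is flat between 300 and
550 mm and then declines by 1 logit per 100 mm up to 700 mm, and the
size–capture curve rises by 0.8 logits per 100 mm up to a 500 mm plateau —
shapes that make spline recovery a real test rather than a formality.
Covariates come from normal generators (air temperature 15 ± 3.5 °C,
humidity 75 ± 10%) with a 20% precipitation frequency.

Two generators cover the two data types.  The CMR generator
(`simulate_states_and_detections()`) simulates the latent three-state
process and daily detections, conditioning the dataset on first capture
exactly as the model does.  The growth generator
(`simulate_remeasurement_events()`) draws remeasurements from the growth
model's own Markov structure — each observed length is normal around the
von Bertalanffy projection of the *previous observed* length — because
that is the structure the growth likelihood assumes; simulating an
error-free latent trajectory with independent noise instead would be an
errors-in-variables misspecification of the very model under test, and
measurably biases $\sigma_e$ upward.

What the generator does *not* emulate: trap-array geometry and movement,
density dependence, covariate imputation from gridded weather products,
individual heterogeneity in capture probability beyond size, and
Markovian (state-dependent) emigration.  Passing recovery tests therefore
show the estimation machinery is correct for data from this generative
family, not that field data satisfy its assumptions.

## Numerical choices and degenerate inputs

* Elapsed times are integer day counts divided by 365.25; survey-window
  midpoints anchor between-primary intervals.
* The forward pass works on linear-scale state masses; with daily
  detection probabilities of order 0.01–0.05 and at most 14 primaries the
  masses stay far from underflow, and a zero total returns `-Inf` rather
  than `NaN`.
* Proposals implying a non-positive asymptote are rejected outright
  (outside the kernel's domain).
* Apparent shrinkage between captures beyond three residual SDs triggers a
  warning, not an error — shrinkage within measurement noise is expected.
* Individuals first captured in their site's final year are removed from
  the CMR data (they carry no survival information); removing everyone
  yields an empty dataset with an explicit warning.
* Duplicate (individual, date) capture rows and unparseable dates are
  errors that name the offending row; missing survey covariates are errors
  because covariate imputation is out of scope.

## Problem sizes used by the checks

The recovery study fits 10 replicates of: a five-site growth survey with
≈260 increments from ≈240 remeasured individuals (five sites, matching the
emulated study's growth-data design — with only two sites the sex-site
asymptote hierarchy has four cells and the grand mean is barely separable
from the site effects), and a CMR study with 2 sites, 5 and 4 primary
periods, 15 occasions per period, and a superpopulation of 280 (≈30–60
detected individuals enter the CMR likelihood), with 2 chains ×
(600–900 warm-up + 700–1,000 draws).  These sizes were chosen as the
smallest at which 95% interval coverage of the generating truth is a
meaningful check; the acceptance script runs one deeper two-stage analysis
(≈310 increments; 8- and 5-year CMR-style sites at 15–20 occasions) with
2 chains × (1,200 warm-up + 2,000 draws).

## Known limitations

* The growth stage conditions on the previous *observed* length; the CMR
  stage propagates a deterministic latent trajectory.  The two
  formulations agree in expectation but make different error assumptions;
  the stage-2 prior inflation absorbs part of the difference.
* Availability, survival and capture intercepts are weakly identified when
  recapture rates are very low; posteriors then lean on their priors, and
  interval widths say so.
* The sampler is a general-purpose adaptive random-walk scheme: robust,
  reproducible, but not the fastest-mixing option for strongly correlated
  posteriors.  R-hat flags in `convergence_report()` should be consulted
  before quoting tail quantiles.
* `rho_k_phi` (growth–survival year-effect correlation) needs many years
  to be informative; with short series its posterior is close to its
  uniform prior.
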