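# vbcmr

Integrated growth and survival modelling for size-dependent demography in
capture–mark–recapture (CMR) studies of elusive animals.

## The problem

In many reptiles and amphibians, survival, capture probability, and even
presence on a study site depend on body size — but for species with low
recapture rates (the motivating case is an endangered gartersnake surveyed
with daily funnel-trap checks each spring), an individual's size is
unknown in almost every year after its first capture. Treating size as an
ordinary covariate is then impossible, and assuming a linear size–survival
relationship can badly misspecify the biology.

`vbcmr` fits, in a single Bayesian framework:

- a **hierarchical von Bertalanffy growth model** on recapture length data,
  `E[L_t] = a − (a − L_{t−1}) exp(−(k/a) Δt)`, with sex and site effects on
  the asymptote `a`, and sex, site, year, and individual effects on
  `log k`;
- a **three-state robust-design Cormack–Jolly–Seber model** (available /
  temporarily unavailable / dead-or-emigrated, random emigration) for
  annual apparent survival `φ`, daily capture probability `p`, and
  availability `γ`, with the growth model embedded so each individual's
  latent size is propagated — with uncertainty — through every primary
  period;
- **penalized low-rank spline** size effects on `φ` and `p`
  (truncated-power basis, 5 quantile knots, cubic, coefficients shrunk by a
  shared SD), and a linear size effect on `γ`;
- survey-condition effects on `p` (air temperature, humidity, day of year,
  precipitation), correlated annual random effects on growth and survival,
  latent sizes for unmeasured individuals and latent sex indicators for
  unsexed ones;
- posterior predictive checks (residual sum of squares for growth,
  Freeman–Tukey on recapture counts for the CMR model), split-chain R-hat
  diagnostics, and derived quantities such as the annualized recapture
  probability `p* = 1 − (1 − p)^J` and size-at-age trajectories;
- a **synthetic-data generator** that simulates individuals, growth, latent
  states, surveys and detections from the same model equations, so every
  stage of the pipeline can be exercised and validated by parameter
  recovery without field data.

The latent-state likelihood is marginalized with a forward algorithm
(C++ core), which automatically implements the rule that individuals not
available for capture carry no information about `p`.

## Worked example

Simulate a five-site growth survey and a two-site CMR study at the default
demographic truth, fit both stages, and summarize:

```r
library(vbcmr)

# growth survey: five sites of remeasurement data
cfg_g <- simulation_config(
  sites = c("N", "C", "S", "I", "P"),
  start_year = c(N = 2014, C = 2009, S = 2014, I = 2011, P = 2015),
  n_years = c(N = 4, C = 7, S = 4, I = 5, P = 4),
  occasions_per_year = 15L,
  n_individuals = c(N = 45, C = 70, S = 45, I = 50, P = 40))
gd  <- simulate_remeasurement_events(cfg_g, seed = 1)
inc <- build_growth_increments(gd$events)   # 261 increments
gfit <- fit_growth(inc, mcmc = mcmc_config(chains = 2, draws = 1000,
                                           warmup = 900), seed = 1)
summary_table(gfit$draws, c("upsilon_f", "theta_m", "mu_a_m", "mu_f",
                            "sigma_e"))

# CMR study: detections at two long-term sites, with the growth
# posterior as informative prior
cfg <- simulation_config(
  n_years = c(C = 6, I = 4), start_year = c(C = 2010, I = 2012),
  occasions_per_year = 20L, n_individuals = c(C = 250, I = 150))
sim <- simulate_study(cfg, seed = 2)
ds  <- filter_cmr_individuals(sim$dataset)  # 100 individuals enter the CMR
cfit <- fit_cmr(ds, growth_stage1 = gfit,
                mcmc = mcmc_config(chains = 2, draws = 1000,
                                   warmup = 800), seed = 3)
summary_table(cfit$draws, c("phi_mean[female.C]", "phi_mean[male.C]",
                            "lambda_gamma", "delta_p[precip]"))

# annualized recapture probability over a 52-day season, and fit checks
mean(annual_recapture_prob(draws_of(cfit$draws, "p_mean[female.C]"), 52))
ppc_growth(gfit, seed = 4)$p_value
ppc_cmr(cfit, seed = 4)$p_value
```

Output for these seeds:

```
  parameter      mean       sd      q2.5     q97.5
1 upsilon_f  756.8128  8.31125  741.3788  773.4612
2   theta_m -189.7761 10.44128 -208.2485 -168.2804
3    mu_a_m  567.0366  6.84240  554.3958  580.5668
4      mu_f    5.0033  0.35823    4.2973    5.7143
5   sigma_e   25.3115  1.61451   22.5315   28.9114

           parameter    mean     sd   q2.5   q97.5
1 phi_mean[female.C]  0.8113 0.1622  0.362  0.9847
2   phi_mean[male.C]  0.8116 0.1641  0.385  0.9898
3       lambda_gamma -0.1227 0.9756 -2.070  1.7973
4    delta_p[precip] -0.8258 0.3880 -1.557 -0.1421

p* female C: 0.65657
growth ppc: 0.496
ft ppc: 0.4533333
```

The generating truth is: female asymptote 737 mm, male effect −187 mm, log
growth coefficient 5.55, residual SD 23.3 mm, female survival 0.66 at
site C, precipitation effect −0.65, availability slope +0.49 per SD of
SVL.  Most 95% intervals cover their truth (the male effect, growth
coefficient, residual SD, survival, availability slope, precipitation
effect); the asymptote interval for this seed sits a few millimetres high
— with many parameters and 95% intervals, occasional near-misses are
exactly what calibrated uncertainty looks like, and the ten-replicate
recovery study in the test suite verifies ≥8/10 coverage for every
headline parameter.  The PPC p-values land near 0.5, as they should on
model-true data.

## Command line

A thin dispatcher over the same functions ships in
`inst/scripts/vbcmr` (subcommands `simulate`, `fit-growth`, `fit-cmr`,
with `--check` for posterior predictive output and size curves).
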