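---
title: "Seasonal dynamic occupancy models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal dynamic occupancy models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynocc)
```

This vignette is the package's account of the statistical machinery:
the model and its assumptions, the inference engine, the
goodness-of-fit construction, the synthetic-data generator, and the
design decisions that were genuinely open when the package was written.

## The model

`dynocc` fits a two-level hierarchical model to monthly camera-trap
detection histories arranged in alternating summer and winter *primary
seasons* (the robust-design layout: the latent state may change between
seasons but is assumed constant across the months within one).

**Process level.** Each site $i$ carries a latent binary *use* state
$z_{i,t}$ per season $t$ ("use" rather than "occupancy" because a
camera station samples only a fraction of a large mammal's home range,
and "desertion" rather than "extinction" for the same reason):

$$z_{i,1} \sim \mathrm{Bern}(\psi_{i,1}), \qquad
  z_{i,t} \sim \mathrm{Bern}\!\big(z_{i,t-1}(1-\varepsilon_{i,t-1}) +
  (1-z_{i,t-1})\,\gamma_{i,t-1}\big),$$

with colonization probability $\gamma$ and desertion probability
$\varepsilon$ indexed by the *origin* season of each transition.
Because seasons alternate strictly, conditioning $\gamma_{i,t}$ and
$\varepsilon_{i,t}$ on the origin season's label makes the season
coefficient exactly the winter-to-summer vs summer-to-winter transition
contrast, which is the quantity of ecological interest.

**Observation level.** In month $j$ of season $t$ the species is
detected with probability $z_{i,t}\, p^*_{i,j,t}$, where
$p^*_{i,j,t} = 1 - (1-p_{i,t})^{d_{i,j}}$ compounds a per-day detection
probability $p$ over the $d_{i,j}$ camera-active days of that month.
Months without effort are missing and contribute no observation term.

**Linear predictors.** All four probabilities are logit-linear.
$\psi \sim$ habitat $\times$ population density and $p \sim$ season
$\times$ habitat in every variant; the transition predictors define the
three variants (`additive`, `interaction_popden`,
`interaction_elevation`, see `occu_model()`). Categorical covariates
use treatment coding; the reference levels are broad-leaved forest and
summer — the coding is a convention that had to be fixed once, chosen
alphabetically for habitat, and it affects only the parameterization,
not the fitted probabilities. Continuous covariates (elevation, rural
human population density) are standardized to mean 0, sample (n−1)
standard deviation 1; the constants are stored so predictions can be
annotated on the raw scale. Every predictor receives an independent
random area intercept $u_{a} \sim N(0, \sigma)$ with its own scale
$\sigma$; nothing in the model ties the four offsets of an area
together, since any correlation structure among them would be an
additional assumption we cannot check at these group counts (10 areas).

**Priors.** Standard logistic on intercepts, standard normal on
slopes, half-normal(1) on the four random-effect scales (interpreting
the conventional "normal(0,1) truncated at zero on random effects" as a
prior on the scale parameter, the standard hierarchical reading), and
$N(0,\sigma)$ on the offsets given the scale. All scales are
overridable through `occu_priors()`. On the probability scale the
logistic(0,1) intercept prior is exactly uniform, which is why it is
used instead of a normal.

## Likelihood and sampler

The per-site likelihood is a two-state hidden Markov chain over at most
22 seasons, so the latent states are summed out *exactly* with the
forward algorithm rather than sampled by data augmentation. The
marginalized posterior has only continuous parameters, which any
general-purpose MCMC scheme can traverse, and mixes far better at desk
scale than Gibbs sampling over thousands of binary states; the
posterior over the continuous parameters is identical. Latent states
are recovered after the fact by forward-filter backward-sampling
(`sample_latent_states()`), which draws from the exact conditional
distribution of $z$ given data and parameters — a season with a
detection has $z = 1$ with probability 1.

The sampler (`dynocc()`) is blockwise adaptive random-walk Metropolis,
written in C++. One block per linear predictor moves its fixed
coefficients, its log random-effect scale and its raw area offsets
jointly; these are the parameters the posterior correlates most
strongly, while cross-predictor correlations are weak. Each block
adapts an empirical proposal covariance and a Robbins–Monro-tuned
scale (target acceptance 25%) during burn-in and is frozen afterwards,
so the retained chain is a valid Markov chain. Two reparameterizations
keep the geometry benign: scales are sampled on the log scale (with the
Jacobian), and offsets are non-centered ($\text{offset} = \sigma u$,
$u \sim N(0,1)$), which removes the funnel that centred random effects
produce when $\sigma$ is small.

Numerical guards: all probability logs go through
`log1p`/`softplus`/log-sum-exp forms; in particular
$\log p^* = \log(-\mathrm{expm1}(d \log(1-p)))$, which stays accurate
when a full month of effort pushes $p^*$ within $10^{-12}$ of 1.
Chains start from dispersed, data-informed values (intercepts anchored
at the naive use fraction and the crude per-day detection rate), which
shortens burn-in substantially on detection-sparse data.

`iter` counts sweeps including burn-in; retained draws are
`chains * (iter - burnin) / thin`, and `check_mcmc_config()` exposes
that arithmetic (a production-scale configuration of 3 chains,
1,000,000 iterations, 100,000 burn-in and thinning 20 retains 135,000
draws). The default desk-scale configuration (4 chains, 30,000 sweeps,
10,000 burn-in, thin 10) is sized for simulation studies of ~100 sites
and ~10 seasons; the examples in this package that need tight
convergence of the detection block use 40,000–60,000 sweeps.
Convergence is reported as split-chain R-hat (`diagnose()`): each chain
is halved before the between/within comparison, so within-chain drift
is detected; we use the plain split statistic rather than the
rank-normalized refinement, which matters only for heavy-tailed
posteriors that these bounded-probability models do not produce.

## Goodness of fit

The posterior-predictive check (`occu_gof()`) scores the *closed*
(detection) and *open* (transition) model parts separately with
chi-square discrepancies. The cell structures are this package's own
reconstruction — they are the natural sufficient summaries of each
sub-model, not a transcription of any published code:

- **Closed:** for every surveyed site-season, the observed number of
  detection months against its expectation
  $e = z \sum_j p^*_j$, scaled by a binomial-style variance plus a
  stabilizer $c = 0.5$ that guards cells with near-zero expectation.
- **Open:** for every transition, the colonization and desertion event
  counts among the at-risk sites against $\sum \gamma$ and
  $\sum \varepsilon$, scaled the same way.

For each posterior draw the observed discrepancy conditions $z$ on the
data. The replicated side *mirrors that conditioning*: a full dataset
(states and detections, with the observed effort and missingness
pattern) is simulated from the draw, the latent states are
re-conditioned on the replicated detections, and the same statistic is
computed. Without this mirroring the observed side is systematically
smoother than the replicated side and the Bayesian p-value
$\Pr(\chi^2_{rep} > \chi^2_{obs})$ drifts from 0.5 even under the true
model. With it, the test bench's calibration checks (correct-model
simulate–fit–GoF cycles) give mean open- and closed-part p-values close
to 0.5 and lack-of-fit ratios $\overline{\chi^2_{obs}}/\overline{\chi^2_{rep}}$
close to 1.

## Derived quantities

`proportion_used()` draws $z$ conditional on the data for each
posterior draw and averages over sites, per season — the latent-state
route, not a plug-in of posterior-mean rates, so the intervals reflect
state uncertainty and collapse to the data as detection becomes
certain. `response_curve()` evaluates the colonization or desertion
predictor along a covariate grid for each season label at the "typical
area" (random offset 0) and all other covariates at their standardized
mean, the conditional-prediction convention used for figure-style
covariate effects; it deliberately does not average over areas.

## The synthetic-data generator

`simulate_occu()` generates data from exactly the process above, so
every pipeline stage is testable without field data (none are shipped
with this package). What it emulates: the full survey geometry
(`paper_shape`: 171 stations in 10 areas, 11 winters of 4 months
alternating with 11 summers of 6 months — 110 survey months starting in
winter, a contiguous 35-month gap block plus ~3% sporadic malfunction
months); area-clustered covariates (area-level means for elevation and
population density, per-area habitat composition) mimicking spatial
clustering; and per-month effort drawn uniformly from 20–31 days,
reflecting cameras serviced roughly every six weeks. Missingness is
applied to detections and effort jointly after generation, so a missing
month always has zero effort.

What it does *not* emulate: spatial autocorrelation beyond the area
level, animal movement and home-range structure (detections are
conditionally independent across months given $z$), temporal covariate
change (covariates are static site properties), observer effects, and
misidentification. Passing calibration and recovery tests on these data
therefore certify the *implementation* — that the estimator recovers
the process that generated the data — not that the model is adequate
for any particular field dataset; that question is what `occu_gof()` is
for. Generating effect sizes in the presets were chosen once for test
power (clearly detectable at 100 sites) rather than to mimic any
particular species: e.g. `strong_seasonality` uses a season contrast of
+2.2 on colonization and −2.0 on desertion logits and a per-day
detection intercept of −3.5, giving monthly detection probabilities
around 0.4–0.5 for a used site at reference levels.

## Test-bench sizes and the open design calls

The simulation studies in the test suite are sized to certify
correctness at desk scale: likelihood oracles run on 8 sites × 4 short
seasons (small enough for exhaustive enumeration of all $2^T$ state
paths, agreement to $10^{-10}$); convergence and directionality on 100
sites × 10 seasons; goodness-of-fit calibration and coverage on 50
sites × 8 seasons with 10–20 replicates. Interval-coverage replicates
draw their generating coefficients from the model's own priors, which
makes the nominal 95% coverage of credible intervals exact and the
binomial reference band valid; fixed "representative" truths would
leave a systematic coverage offset that no sample size could wash out.

Decisions that were genuinely open, and the calls made:

- **Interaction completeness:** the habitat-by-population-density
  interaction in $\psi$ uses all three habitat contrasts (the full
  factorial), the literal reading of the model formula.
- **Random-effect structure:** one independent offset per predictor and
  area, each with its own scale (four scales), rather than offsets
  shared across predictors.
- **Transition covariate timing:** season covariates for transitions
  come from the origin season (equivalent, under strict alternation, to
  labelling transitions by direction).
- **Burn-in accounting:** burn-in is counted inside the total iteration
  budget, the only reading under which the production retained-draw
  arithmetic (135,000 from 3 × (1,000,000 − 100,000)/20) is consistent.
- **Survey-gap emulation:** the long mid-survey gap is a contiguous
  35-month block of modeled months (a 43-calendar-month gap loses its
  transition months, which are not part of the month grid).

## Limitations

- Only the three fixed model variants are supported; there is no
  free-form formula interface, no spatial autocorrelation, and no
  multi-species joint model.
- The random-walk sampler is robust but not gradient-based; posteriors
  with thousands of parameters (hundreds of areas) would mix slowly.
- Model comparison is by goodness of fit only; no information criteria
  are computed.
- The chi-square cell structure is a reconstruction (see above);
  Bayesian p-values from different cell structures are not comparable
  across implementations.
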