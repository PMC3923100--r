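---
title: "Comparing centre-adjustment methods for binary multicentre trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing centre-adjustment methods for binary multicentre trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a multicentre randomised trial, patients recruited at the same centre
tend to be more alike than patients from different centres: case mix,
local practice, and baseline risk all vary between hospitals. When the
outcome is binary and analysed as an odds ratio, the natural way to
quantify this clustering is the intraclass correlation coefficient (ICC)
on the latent logistic scale,

$$\mathrm{ICC} = \frac{\sigma^2}{\sigma^2 + \pi^2/3},$$

where $\sigma^2$ is the between-centre variance of the centre effects and
$\pi^2/3$ is the variance of a standard logistic error. Ignoring centre
in the analysis after centre-stratified randomisation inflates the
standard error of the treatment effect by $(1-\mathrm{ICC})^{-1/2}$;
`power_reduction_unadjusted()` turns that inflation into the attained
power of a trial designed for, say, 80% power. The loss is negligible at
ICC 0.01 (0.4 percentage points) but material at 0.10 (4.3) and 0.25
(12.1).

The harder question is *how* to adjust. Each of the standard choices
fails in some corner of the design space - too many small centres, rare
events, few clusters - and this package exists to map those corners by
simulation.

## The generative model

`generate_trial()` draws data from a latent-variable model. For patient
$i$ in centre $j$,

$$Y^*_{ij} = \alpha + \beta_{treat} X_{ij} + \textstyle\sum_k \beta_k
Z_{kij} + u_j + \varepsilon_{ij}, \qquad Y_{ij} = \mathbf{1}\{Y^*_{ij} > 0\},$$

with $u_j \sim N(0, \sigma^2)$ independent across centres,
$\varepsilon_{ij}$ standard logistic independent across patients, and
$u$ and $\varepsilon$ generated independently. This is exactly
equivalent to drawing $Y_{ij} \sim
\mathrm{Bernoulli}(\mathrm{expit}(\alpha + \beta_{treat} X_{ij} + \sum_k
\beta_k Z_{kij} + u_j))$, an identity the test suite checks
distributionally. Two calibrations connect the model to trial-design
language:

* **Control event rate.** `calibrate_alpha(rate)` sets
  $\alpha = \mathrm{logit}(rate)$, i.e. the *conditional* (at $u_j = 0$)
  control-arm log-odds rather than the marginal rate averaged over
  centres. We chose the conditional convention because the MIST2-like
  generator takes its intercept directly on the log-odds scale
  ($\alpha = -3.3$), and at the ICCs in the study grids
  (0.025-0.25) the conditional-marginal gap in the event rate is
  under one percentage point. The marginal rate implied by any
  $(\alpha, \sigma)$ pair can always be obtained by numerical
  integration, as done in the generator tests.
* **Effect size.** `calibrate_effect()` returns the event-*reducing*
  log odds ratio at which a two-sided 5% two-proportion z-comparison
  with $n/2$ patients per arm attains 80% power, solved numerically on
  the log-odds scale. Clustering is deliberately ignored here: this is
  the conventional design calculation a trial statistician would run,
  and the study's power rows are defined relative to it. Power
  calibration is a convention, not a unique mapping - different
  normal-approximation variants shift the calibrated odds ratio slightly
  - so simulated power values carry a calibration-convention band of a
  few percentage points on top of Monte-Carlo error when compared across
  implementations.

## Randomisation

`simple_randomization()` is an independent fair coin per patient.
`stratified_permuted_blocks()` balances arms within centre using blocks
of 4 or 20 (any even size is accepted): each complete block contains
exactly half treated, and when a centre's size is not a multiple of the
block length the final block is a randomly permuted full block truncated
to the remaining patients, keeping the within-centre imbalance at or
below half a block.

Patient allocation over centres is either *even* (sizes differ by at
most one, remainder to the lowest-indexed centres) or *skewed*. The
skewed scheme is a declared synthetic profile: 10% of centres (rounded
up, at least one) share half the patients equally, the rest share the
other half. It represents the recruitment pattern seen in many real
multicentre trials - most patients concentrated in a few centres - and
any exact size vector observed in a real trial can be passed straight
to `generate_trial()` instead.

## The five estimators

All estimators consume the same per-patient `trial_dataset` and return
the same `estimate_result` (treatment log odds ratio, SE, 95% CI,
p-value, patients included, convergence flag), which keeps the
simulation engine method-agnostic.

* **Unadjusted logistic** (`unadjusted_logistic()`): ML logistic
  regression on treatment (plus covariates), no centre terms, Wald
  inference.
* **Fixed-effects** (`fixed_effects_logistic()`): adds an indicator for
  every centre but one. Centres whose patients all share one outcome or
  one arm contain no within-centre information; they are excluded
  *before* fitting - this makes the number of analysable patients
  reportable and prevents separation-driven optimiser failures from
  masquerading as method breakdown - and `n_included` reflects the
  exclusions.
* **Random-effects** (`random_effects_logistic()`): logistic regression
  with a normal random intercept per centre. The marginal likelihood is
  maximised with the intercept integrated out by adaptive Gauss-Hermite
  quadrature: per centre, the integrand is re-centred at its conditional
  mode and scaled by the local curvature before applying the
  Gauss-Hermite rule. Twelve nodes are the default (a long-standing
  default in commercial mixed-model software);
  estimates are invariant to refinement to 30 nodes within $10^{-4}$ on
  the suite's fixtures, and the fit agrees with `lme4::glmer` at equal
  node counts to $10^{-4}$. All centres and patients contribute. The
  fitted $\hat\sigma$ is exposed so the empirical ICC can be reported.
* **GEE** (`gee_logistic()`): population-averaged logistic regression
  with an exchangeable working correlation, solved by Fisher scoring on
  the quasi-score. The working correlation is re-estimated each
  iteration by the moment estimator from Pearson-residual
  cross-products (denominator corrected for the parameter count, scale
  fixed at 1), exploiting the closed-form inverse of an exchangeable
  correlation matrix so no per-cluster matrix inversion is needed.
  `se_type = "naive"` gives the model-based covariance; `"robust"` the
  sandwich. The sandwich is verified in tests against a brute-force
  per-cluster matrix evaluation to $10^{-10}$.
* **Mantel-Haenszel** (`mantel_haenszel()`): the classical stratified
  odds ratio
  $\mathrm{OR}_{MH} = \sum_j (a_j d_j / n_j) \big/ \sum_j (b_j c_j / n_j)$
  over per-stratum 2x2 tables. Strata come from `build_strata()`, the
  cross-classification of centre and categorical covariates (continuous
  covariates must be cut first - the categorisation cost is one of the
  method's documented drawbacks). Non-informative strata (single arm or
  single outcome) contribute nothing and their patients are dropped from
  `n_included`.

### Conditional versus marginal

The fixed-effects, random-effects, and MH estimates are *conditional*
(centre-specific) odds ratios; GEE estimates the *marginal*
(population-averaged) one. With a non-zero ICC and a real effect the
marginal odds ratio is attenuated toward 1 relative to the conditional
one, so the two families answer different questions and their estimates
should not be compared numerically - a property the test suite asserts
on simulated data.

### Inference conventions

Wald tests and intervals (log scale, $\pm 1.96\,\mathrm{SE}$) are used
for every regression method, matching the $p < 0.05$ rejection rule of
the simulation study. For Mantel-Haenszel the CI comes from the
Robins-Breslow-Greenland variance while the p-value comes from the MH
chi-square test (1 df, no continuity correction). These two rest on
different information, so a p-value can cross 0.05 while the CI still
covers 1 - the same structural inconsistency that standard stratified
routines in commercial statistics packages produce. The
RBG/MH-chi-square pairing is this package's declared convention; it is
the standard pairing, not a verified match to any particular
implementation.

### Convergence

`convergence_check()` encodes the study's failure rules: a fit is
declared non-converged when the optimiser signalled failure, when the
absolute treatment log odds ratio or its SE exceeds 1000, or when both
are exactly zero (treatment dropped). Scenario summaries
(`summarize_estimates()`) compute the mean treatment effect
(exponential of the mean log odds ratio), rejection rate, and their
Monte-Carlo SE over *converged* replicates only, and flag a scenario
with no converged replicates with `NA` rather than zeros.

## The MIST2-like fixture

`generate_mist2_like()` emulates a two-arm version of an 11-centre
pleural-infection trial: 190 patients with centre sizes
1/3/5/8/10/12/14/15/16/19/87 (median 12, range 1-87; only those summary
statistics of the real trial are public, the full size vector is
synthetic), simple randomisation, and outcomes from the latent model
with $\alpha = -3.3$ and covariate coefficients 0.03 (pleural fluid, per
percentage point), $-0.2$ (purulence), 0.4 (hospital-acquired
infection). The covariate distributions are likewise synthetic stand-ins
- the real patient-level data are not deposited - chosen once and fixed:
pleural fluid $100\,\mathrm{Beta}(1.55, 2.45)$ (right-skewed, mean 39%),
purulence Bernoulli(0.5), hospital-acquired Bernoulli(0.2), tied by a
Gaussian copula with correlation 0.2. The Beta shape was selected by
numerical integration so the marginal event rate at the printed
coefficients equals the trial's reported 12%; the treatment odds ratio
is configurable (1 or 0.23 in the study pair, via `build_mist2_grid()`).

What this fixture does *not* capture: the real joint covariate
distribution (resampling real patient records would preserve it, but
the records are not available), the real centre-size vector, the
four-arm structure, and the minimisation scheme used in the actual
trial. Results on it therefore support
qualitative claims (e.g. MH drops far more patients than fixed-effects,
which drops more than random-effects/GEE) but not a numerical
reproduction of the original reanalysis table.

## Scenario grids and the simulation engine

`build_main_grid()` enumerates the full factorial: centres
$\{5, 50, 100\}$ x patients $\{200, 500, 1000, 2000\}$ x ICC
$\{0.025, 0.075\}$ x distribution $\{even, skewed\}$ x control event
rate $\{20\%, 50\%\}$ x block size $\{4, 20\}$ = 192 scenarios, each run
under the null (OR 1) and under the calibrated 80%-power effect.
`build_icc_sensitivity()` (24 scenarios at ICC 0.25) and
`build_robust_gee_sensitivity()` (12 scenarios analysed with the
sandwich SE) provide the study's sensitivity analyses.

`run_scenario()` executes one configuration: per replicate it derives a
substream seed from `(base_seed, scenario_id, replicate)` via a mixed
congruential key (unique for replicate indices below 16807, so no two
replicates anywhere in a run share a stream, and results are
order-deterministic however replicates are scheduled), randomises,
generates, fits every requested method on the *same* dataset, applies
the convergence rules, and aggregates. Power runs offset the scenario id
by 1000 so they never reuse null-run streams.

### Problem sizes and runtime

The study ran 5000 replicates per scenario (Monte-Carlo SE about 0.3
percentage points on a 5% rate). The package defaults its grid builders
to 1000 replicates, a desk-scale setting at which a full
type-I-error-plus-power pass over one 16-scenario slice takes a few
minutes on one core; the reproduction script
(`scripts/acceptance.R`) uses 5000 replicates for the type-I-error runs,
whose targets are extreme-order statistics (a maximum or minimum over 16
scenarios) and therefore benefit most from small Monte-Carlo error, and
1500 for the power runs, whose targets carry the wider
effect-calibration band. All replicate counts are ordinary arguments.

## Numerical choices

* Mixed-model optimisation: `nlminb` on $(\beta, \sigma)$ with
  $\sigma \ge 0$, relative tolerance $10^{-10}$, at most 200 iterations,
  one restart from a near-boundary $\sigma$ before declaring optimiser
  failure. At a boundary solution ($\hat\sigma \approx 0$) the Wald SE
  comes from the fixed-effect block of the Hessian with $\sigma$ held
  fixed, since the full Hessian is singular there.
* GEE: coefficient-change tolerance $10^{-8}$, at most 100 iterations;
  the working correlation is clamped to $(-0.95/(m_{max}-1),\, 0.95)$ to
  keep every cluster's working covariance positive definite; clusters of
  size 1 degrade exactly to ordinary logistic regression (tested to
  $10^{-8}$).
* Gauss-Hermite nodes are computed by the Golub-Welsch eigenvalue method
  and cached per node count.
* Ties and degenerate inputs: all-event or all-non-event datasets are
  non-estimable for every method and reported as such rather than
  erroring; a single informative centre reduces the fixed-effects model
  to the unadjusted one.

## Known limitations

* The skewed allocation and the MIST2-like covariate distributions are
  declared stand-ins, not recoveries of the unpublished originals.
* Only two arms, no treatment-by-centre interaction, no unequal
  allocation, and no minimisation - matching the scope of the simulation
  study, not the full design space of real trials.
* Conditional logistic regression, propensity scores, permutation tests,
  Firth correction, and likelihood-ratio/score intervals are out of
  scope.
* Data are generated under the random-effects model, which may flatter
  the random-effects analysis; evidence from continuous-outcome settings
  (where random-effects analyses beat fixed-effects even on data
  generated under a fixed-effects model) suggests conclusions are
  unlikely to hinge on this, but the caveat stands for binary outcomes.
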