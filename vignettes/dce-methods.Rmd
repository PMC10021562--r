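---
title: "Methods: choice-experiment design, estimation and risk-correlate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choice-experiment design, estimation and risk-correlate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcekit)
```

## The model

`dcekit` analyses stated-preference discrete choice experiments (DCEs)
with a random utility model. Respondent $i$ facing choice set $c$ derives
utility $U_{ijc} = X_{ijc}\beta + \varepsilon_{ijc}$ from alternative
$j$; the package assumes independent type-I extreme value (Gumbel) errors
— the assumption that makes the familiar multinomial (conditional) logit
choice probability

$$P_{ijc} = \frac{\exp(X_{ijc}\beta)}{\sum_{J}\exp(X_{ijc}\beta)}$$

exact rather than approximate. The study instrument this package is built
around describes hypothetical tourist partnerships for Gambian men working
on the tourist beaches: five attributes (condom use, money in Gambian
dalasi, timing of the money transfer, relationship length, partner age),
eight tasks, two unlabelled profiles per task and a "neither" opt-out
carrying its own constant.

Categorical attributes are *effects coded*: an $L$-level attribute
contributes $L-1$ columns, level $k<L$ is the unit vector, and the
last-listed level is the reference coded $-1$ throughout, so estimated
level utilities sum to zero within each attribute and the reference
utility is recoverable as minus the sum of the contrasts
(`level_utilities()` does this expansion). The instrument does not say
which level the original analysis used as its base; fixing the
*last-listed* level is this package's convention, chosen because it is
deterministic and recoverable from the attribute configuration alone.
Money can instead be coded as one continuous per-GMD column
(`recode_continuous()`), which is the form willingness-to-accept ratios
require.

## Design generation

`search_efficient_design()` minimises the local D-error
$\det I(\beta_0)^{-1/K}$, where $I$ is the MNL Fisher information of the
coded design at prior coefficients $\beta_0$ and $K$ the parameter count.
Because the source analysis mentions point priors from a small pilot and
no prior distribution, the criterion is the local D-error, not a Bayesian
$D_b$-error. The search is a coordinate (profile) exchange: starting from
a seeded random level-balanced design (`pilot_design()`, which also
stands in for the orthogonal pilot array when no orthogonal array of the
exact size exists — the construction is flagged in the design metadata),
each task-by-alternative slot is exchanged against every candidate of the
full factorial, accepting only strict improvements, until a sweep changes
nothing; the best of `n_restarts` restarts wins. Acceptance only on
strict decrease makes the D-error trajectory monotone non-increasing, and
on candidate spaces small enough to enumerate the search attains the
exhaustive minimum (both properties are tested). A singular information
matrix — for instance both profiles identical in every task — is reported
as an infinite D-error with a `singular` attribute rather than an error.

## Estimation

`fit_mnl()` maximises the MNL likelihood by Newton ascent with step
halving from a zero start; the log-likelihood is globally concave, so
iteration stops when the analytic gradient's max-norm falls below
`tolerance` (default `1e-6`). Standard errors come from the inverse
observed information, with respondent-clustered sandwich errors by flag
(the source analysis is silent on clustering, so unclustered is the
default). Coefficients running beyond 10 in absolute value on the coded
utility scale are flagged as divergent — under separation the gradient
decays exponentially along the runaway direction, so a small gradient
alone cannot certify an interior maximum.

`fit_mmnl()` adds normally distributed random coefficients for *all*
parameters (taken literally from the study description, including the
opt-out constant) and maximises the simulated likelihood: per respondent,
the average over draws of the product of that respondent's task-level
choice probabilities, with one coefficient draw spanning all eight tasks.
This panel mixing reflects repeated tasks per respondent; the study does
not state panel versus observation-level mixing, and panel mixing is the
standard choice for repeated tasks. Draws are Halton sequences —
successive primes assigned to parameters in column order, first 10 points
dropped, no scrambling by default — so a fit is exactly reproducible from
`n_draws` and `seed`. SD parameters enter unrestricted and are reported
as absolute values. With all SDs at zero every draw coincides and the
simulated likelihood *equals* the MNL likelihood, a collapse the tests
assert to machine precision. The study specification is 1000 draws;
property tests run far fewer because the collapse and dominance
properties hold at any draw count.

## Willingness to accept

`wta()` computes money-denominated compensation for a utility contrast as
$-\Delta\beta / \beta_{\text{money}}$ with the continuous (per-GMD) money
coefficient as denominator. Attempting the ratio on an effects-coded
money fit is an explicit error: a per-GMD quantity is undefined there,
matching the source analysis's use of its continuous-money model for WTA.
Uncertainty comes from Krinsky–Robb simulation (default 10,000
multivariate-normal parameter draws, 95% percentile interval); draws
whose money coefficient falls below a numeric floor flag the estimate
unstable rather than silently producing enormous ratios. The ratio is
invariant to rescaling all coefficients and to the effects-coding
reference when the contrast is expressed between named levels. For "the
relationship with the tourist in general" the pipeline uses the contrast
$-\beta_{\text{opt-out}}$ — the utility change of giving up the
"neither" option — which is the sign convention that yields a positive
compensation figure from a positive opt-out constant.

## Survey scoring and risk correlates

The WHO-5 wellbeing index is scored on the raw 0–25 scale (not the
percentage scale: the study sample's reported mean of 16.2 is only
consistent with raw scoring), with poor wellbeing defined as under half
the possible score, i.e. total < 12.5. The Household Hunger Scale is
taken as the standard three-question instrument aggregated to 0–6 with
cut-points 0–1 / 2–3 / 4–6 (none-low / moderate / high); the original
supplementary instrument is not available, so the cut-points are
config-overridable. HIV knowledge is a count of nine pre-graded items
with the reporting categories 9/9 (very high) and <6/9 (low).

`fit_risk_models()` fits the five multivariable logistic regressions
(ever had sex with a tourist, condom use at last sex, STI symptoms,
alcohol, recent drug use) on the same eight covariates, by
package-implemented iteratively reweighted least squares
(`fit_logistic_irls()`, gradient max-norm `1e-8`). Listwise deletion is
applied per model; the drugs model is restricted to ever-users.
`detect_separation()` screens categorical covariates for levels that
perfectly predict the outcome — the published drugs model had to omit
household hunger for exactly this reason — and omits them with a
machine-readable reason code before fitting. Odds ratios are
`exp(coefficient)` with Wald intervals, and the pseudo-$R^2$ is
McFadden's (the published table reports an undefined "R-squared"; the
output labels the definition explicitly).

## The synthetic-data generator

No raw choice or survey data are deposited, so the package carries a
generator (`generate_choices()`, `generate_survey()`) whose defaults live
in one configuration file (`inst/extdata/generator_defaults.yaml`), not
in code. The choice side simulates utilities as the coded systematic part
plus inverse-CDF Gumbel draws and takes the argmax, which reproduces the
logit probabilities exactly; mixed-coefficient mode draws one normal
coefficient vector per respondent. The default truth is the published
effects-coded MNL coefficient vector; levels the publication leaves
unprinted are filled by the zero-sum constraint (condom "half of the
time" = 0.031, payment at end of trip = 0, one night = 0.300 — above the
Europe-invitation level, which matches its description as the most
favoured — and money level utilities set monotone increasing). These
fill-ins are conventions, not published values, and are marked as such in
the configuration file.

The survey side draws covariates independently from marginals calibrated
to the published sample description (age truncated normal 39.2/9.58,
40% registered occupation, 85% bill difficulty, 15% moderate-or-high
hunger, WHO-5 total 16.2/4.2, HIV-knowledge categories 47%/28%/25%,
lognormal income and tenure), then draws the five outcomes from logistic
models whose slopes are the published odds ratios on the log scale, with
intercepts calibrated to sample prevalences at covariate means. The
hunger slope of the drugs model is a synthetic stand-in (set to 2.0): the
publication reports that covariate as omitted for complete separation, so
no finite estimate exists. Covariates are generated independently — no
copula — so joint-distribution features of the real sample (e.g.
age-income correlation) are *not* emulated; passing tests therefore
demonstrate correctness of the estimators under the assumed model, not
robustness to real-data dependence structure. What the generator shares
with the loaders is the delimited-text format, round-trip tested.

## Numerical choices and problem sizes

- All randomness funnels through a seed-scoped helper (Mersenne–Twister,
  inversion), leaving the caller's RNG state untouched; identical seeds
  give byte-identical datasets.
- Choice probabilities subtract the per-task maximum utility before
  exponentiating, so no parameter value overflows.
- Ties in simulated argmax choices are broken by first index; with
  continuous Gumbel noise ties have probability zero.
- The parameter-recovery harness (`recovery_experiment()`) runs 50
  replicates of generate-plus-fit at the study scale (242 respondents ×
  8 tasks × 3 alternatives) in a few seconds; per-coefficient means land
  within two Monte-Carlo standard errors of the generating values. The
  mixed-logit recovery check runs at a reduced scale (10 replicates, 200
  draws): simulated maximum likelihood carries a bias of order
  1/draws, so at 200 draws the means are checked to a tolerance of 0.1
  utility units rather than the sharp 2-SE criterion the MNL satisfies.
- Krinsky–Robb intervals clip negative covariance eigenvalues (with a
  warning) rather than fail on marginally non-PSD matrices.

## Limitations

- The realised design of the original fieldwork cannot be reconstructed:
  its pilot priors are unpublished. The package regenerates a design of
  the same shape from stated priors instead.
- Blocked designs, interaction designs, Bayesian efficient designs,
  nested/latent-class logit, correlated random coefficients and WTP-space
  models are out of scope.
- The effects-coded money attribute makes within-attribute nonlinearity
  visible but leaves WTA undefined; the continuous recode trades that
  visibility for a per-GMD denominator. Both fits are one call apart.
- GBP conversions are deliberately not reproduced (the published
  conversion rates are inconsistent between mentions).
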