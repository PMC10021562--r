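# dcekit

Design, estimation and reporting tools for stated-preference **discrete
choice experiments (DCEs)**, built around a health-economics study of
partnership preferences among Gambian men who work with tourists — a
population facing real trade-offs between money, the chance of travel to
Europe, and sexual-health risk. The package covers the full quantitative
workflow of such a study: constructing the choice instrument, estimating
preference weights, converting them to money-denominated compensation,
scoring the accompanying survey instruments, and modelling the correlates
of risk behaviours.

## What it computes

Choices are modelled with a random utility model. Respondent *i* derives
utility from alternative *j* in choice set *c*:

    U_ijc = X_ijc β + ε_ijc,     ε ~ iid type-I extreme value,

which yields multinomial (conditional) logit choice probabilities
`P_ijc = exp(X_ijc β) / Σ_J exp(X_ijc β)`. The instrument has five
effects-coded attributes (condom use, money in GMD, timing of payment,
relationship length, partner age), eight tasks of two profiles plus a
"neither" opt-out. On top of that core the package provides:

- **`search_efficient_design()`** — D-efficient designs (minimum
  `det I(β₀)^(-1/K)` at point priors) by coordinate exchange over the
  full factorial, with `d_error()` and singularity reporting.
- **`fit_mnl()` / `fit_mmnl()`** — maximum likelihood conditional logit
  (analytic gradient and Hessian, Newton ascent) and panel mixed logit
  with normal random coefficients simulated from Halton draws
  (deterministic given `n_draws` and `seed`).
- **`wta()`** — willingness-to-accept ratios `-Δβ / β_money` from a
  continuous-money fit, with Krinsky–Robb percentile intervals.
- **`score_who5()`, `score_household_hunger()`, `score_hiv_knowledge()`**
  — survey-instrument scoring at the study's cut-offs.
- **`fit_risk_models()`** — the five multivariable logistic regressions
  of risk behaviours on a fixed set of eight covariates, via
  package-implemented IRLS with complete-separation detection and
  omission (odds-ratio tables with Wald CIs and McFadden pseudo-R²).
- **`generate_choices()` / `generate_survey()` /
  `recovery_experiment()`** — a calibrated synthetic-data generator and
  Monte Carlo recovery harness, since the study's raw data are not
  public.
- **`run_pipeline()`** — one-call orchestration of design → simulate →
  fit → WTA → scoring → regressions with seeded, hash-stamped artifacts;
  `inst/cli/dcekit.R` wraps it for the shell.

## Worked example

Build the study-shaped design, simulate choices at the study scale from
the packaged coefficient configuration, and fit the conditional logit:

```r
library(dcekit)

cfg    <- generator_config()   # attributes, truth, calibrated marginals
design <- search_efficient_design(cfg$attributes, cfg$beta,
                                  n_tasks = 8, seed = 42)
choices <- generate_choices(cfg, design, seed = 42)
fit     <- fit_mnl(choices)
fit
#> <MNL fit: 242 respondents, 1936 tasks, LL = -2057.641, converged>
#>                       estimate     se
#> condom_use.1            0.5279 0.0685
#> condom_use.2            0.0343 0.0513
#> ...
#> opt_out                 0.4843 0.0554
```

`condom_use.1 = 0.53` is the effects-coded utility of "condom used every
time" (positive: strongly preferred); the opt-out constant `0.48` says
respondents favour "neither" all else equal. Expanding the contrasts
recovers the implied reference levels (utilities sum to zero within an
attribute):

```r
lu <- level_utilities(fit)
lu[lu$attribute == "condom_use", ]
#>    attribute                        level     utility implied
#> 1 condom_use       Condom used every time  0.52787782   FALSE
#> 2 condom_use Condom used half of the time  0.03433467   FALSE
#> 3 condom_use            Condom never used -0.56221249    TRUE
```

Willingness-to-accept needs money as a continuous per-GMD column:

```r
cont <- recode_continuous(choices, "money")
w <- wta(fit_mnl(cont),
         list(attribute = "condom_use",
              from = "Condom used every time",
              to   = "Condom never used"), seed = 42)
w
#> WTA[condom_use: Condom used every time -> Condom never used]
#>   = 4359.4 GMD (95% CI 2881.0 to 8753.1)
```

i.e. in this simulated sample, abandoning condoms entirely would require
about GMD 4,400 in compensation to leave utility unchanged. The survey
side runs the same way: `generate_survey(cfg, seed = 1)` yields scored
respondent records and `fit_risk_models()` the five odds-ratio tables.

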