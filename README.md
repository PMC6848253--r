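# copdsemi

Bayesian two-state semi-Markov modelling of COPD exacerbation onset and
resolution.

## The problem

Exacerbations of chronic obstructive pulmonary disease (COPD) are usually
analysed as event counts (negative-binomial rates). That discards how long
each exacerbation lasts and cannot say *where* a drug acts. `copdsemi`
instead treats a patient's history as an alternating two-state process —
asymptomatic (state 1) and symptomatic (state 2) — in which the sojourn
time in a state follows a parametric distribution whose clock restarts at
every transition (a semi-Markov renewal process). The package is aimed at
pharmacometricians and biostatisticians who want to model exacerbation
trials at the sojourn level: estimate onset and resolution dynamics,
attribute drug effects to a direction, check the model by simulation, and
explore trial designs.

## The model

For transition direction $k \in \{1{\to}2,\ 2{\to}1\}$ and subject $j$, the
sojourn time has hazard $h(t,\theta_{kj},\alpha_k)$ from one of four
families — exponential, Weibull ($h=\theta\alpha t^{\alpha-1}$), Gompertz
($h=\theta e^{\alpha t}$), log-logistic
($h=\alpha(t/\theta)^\alpha/[t(1+(t/\theta)^\alpha)]$) — with the
subject-level scale linked log-linearly to covariates and a frailty:

$$\theta_{kj} = \theta_{0k}\, e^{\eta_{kj}}
  \exp\!\big(\beta_{k0}\log T_j + \textstyle\sum_w \beta_{kw} x_{wj}\big),
  \qquad \eta_{kj} \sim N(0, \sigma_k^2).$$

Censored sojourns contribute $S(t)$, observed transitions $h(t)S(t)$.
Fitting is by MCMC under vague priors (normal(0, 1000) on unconstrained
transforms, gamma(0.001, 0.001) on the frailty precision), with DIC for
family selection, an optional missing-at-random time-to-dropout submodel,
posterior/visual predictive checks with k-means duration binning, and
transition-rate-ratio / transition-probability summaries of drug effects.
Because the motivating trial datasets are access-restricted, the package
ships a calibrated synthetic trial generator that reproduces their
structure (52-week follow-up, ~1.5 exacerbations per subject-year, sparse
dropout); every analysis stage is exercised against it.

## Worked example

Simulate a two-arm 52-week trial (150 subjects per arm, log-logistic
sojourns, a treatment effect of 0.310 delaying onset), fit the two-state
model, and summarise the drug effect:

```r
library(copdsemi)

config <- copd_trial_config(n_per_arm = 150, seed = 1,
                            treatment_beta1 = 0.310)
trial  <- simulate_trial(config)
trial
#> Two-state trial dataset: 300 subjects, 1083 sojourns
#>   arms: 150 active / 150 placebo; 0 dropouts (window 30 days)
#>   exacerbations observed: 386 completed, 11 ongoing at censoring

formula <- two_state_formula("loglogistic", covariates1 = "treatment")
fit <- fit_two_state(trial, formula,
                     sampler_control(chains = 4, draws = 1000,
                                     warmup = 1000, seed = 2))
summary(fit)
#>          parameter   median     q2.5   q97.5 rhat   ess
#> 1         theta0_1 143.9753 1.23e+02 170.116 1.01 348.3
#> 2          alpha_1   1.2593 1.15e+00   1.367 1.03 220.6
#> 3 beta_1_treatment   0.3817 1.42e-01   0.634 1.01 281.1
#> 4         sigma2_1   0.0179 7.12e-04   0.168 1.06  97.5
#> 5         theta0_2   9.4234 8.73e+00  10.121 1.01 225.1
#> 6          alpha_2   2.9603 2.66e+00   3.319 1.01 170.1
#> 7         sigma2_2   0.1029 3.80e-02   0.181 1.01 169.6
```

The onset and resolution shapes (truth 1.34 and 2.97) and the treatment
coefficient (truth 0.310, 95% CI excluding 0) are recovered from 300
subjects. The placebo/active transition-rate ratio on the onset direction
is above 1 — the drug delays exacerbations — and declines with time in
state 1:

```r
rate_ratio(fit, direction = 1, reference = list(treatment = 0),
           alternative = list(treatment = 1), times = c(30, 90, 180))
#>   time median   lo   hi
#> 1   30   1.53 1.17 2.05
#> 2   90   1.39 1.13 1.75
#> 3  180   1.26 1.09 1.49
```

Model checking and design questions follow the same pattern:
`ppc(fit, trial, seed = 3)` and `vpc(fit, trial, seed = 4)` for predictive
checks, `fit_dropout()` / `attach_dropout()` for the dropout mechanism,
`design_experiment()` for subsampling or follow-up truncation, and
`extrapolate()` for predicting long-horizon outcomes from short-study
fits. `run_pipeline("config.yaml")` drives the whole sequence from a YAML
file; see the methods vignette (`vignettes/two-state-model.Rmd`) for the
modelling details and design decisions.

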