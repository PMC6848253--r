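---
title: "A Bayesian two-state semi-Markov model of COPD exacerbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian two-state semi-Markov model of COPD exacerbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

COPD patients alternate between an asymptomatic state (state 1) and a
symptomatic, exacerbated state (state 2). `copdsemi` treats a subject's
exacerbation history as an alternating renewal process: the time spent in a
state before transitioning (the *sojourn time*) has a parametric
distribution whose clock restarts at every transition, so the transition
rate depends on time since state entry rather than calendar time — a
semi-Markov process. Compared with the negative-binomial count analysis
usual in this area, the two-state view uses both the number *and the
durations* of exacerbations, and can attribute a drug effect to a specific
direction (delaying onset, 1→2, or accelerating resolution, 2→1).

Four sojourn-time families are available, each defined by its hazard
\(h(t)\) and survival \(S(t) = \exp(-\int_0^t h)\):

| family | hazard \(h(t)\) | shape domain | time profile |
|---|---|---|---|
| exponential | \(\theta\) | — | constant (Markov) |
| Weibull | \(\theta\alpha t^{\alpha-1}\) | \(\alpha>0\) | log h linear in log t |
| Gompertz | \(\theta e^{\alpha t}\) | \(\alpha\in\mathbb R\) | log h linear in t |
| log-logistic | \(\dfrac{\alpha(t/\theta)^\alpha}{t\,[1+(t/\theta)^\alpha]}\) | \(\alpha>0\) | rises then falls for \(\alpha>1\) |

Note the Weibull scale here is the rate-like \(\theta\) in
\(S(t)=\exp(-\theta t^\alpha)\), not the accelerated-failure-time scale used
by `survreg`/`flexsurv`. A Gompertz shape may be negative, leaving a
never-transition mass \(\exp(\theta/\alpha)\); the simulator then censors
such sojourns at end of follow-up. Time is measured in days throughout.

Subject-level information enters the scale parameter of direction
\(k\in\{1\to2,\,2\to1\}\) through a log-linear link:

\[
\theta_{kj} \;=\; \theta_{0k}\, e^{\eta_{kj}}\,
\exp\big(\beta_{k0}\log T_j + \beta_{k1}x_{1j} + \dots + \beta_{kM}x_{Mj}\big),
\qquad \eta_{kj}\sim N(0,\sigma_k^2),
\]

with \(T_j\) the subject's study length and binary/continuous covariates
(treatment arm, disease stage, smoking, pack-years, season). A likelihood
contribution is \(h(t)S(t)\) for an observed transition and \(S(t)\) for a
sojourn still open at end of follow-up (right-censoring).

### Design choices in the link

*Frailty as a log-normal multiplier.* The subject random effect is declared
as normally distributed, but a normal multiplier on \(\theta\) can be
negative, violating \(\theta>0\). We therefore let
\(\eta_{kj}\sim N(0,\sigma_k^2)\) enter as \(e^{\eta_{kj}}\) — a log-normal
multiplier consistent with the log-linear covariate link and positive by
construction. This is recorded as the canonical interpretation in this
package.

*Frailty on scale only.* Random effects could also act on the shape, but in
practice they are supportable only on the scale; shape frailty is available
as a switch (`shape_frailty = TRUE` on a `transition_spec`) and off by
default.

*The study-length term.* \(\beta_{k0}\log T_j\) accounts for differing
follow-up durations. When every subject shares one study length the column
is constant and \(\theta_{0k}\) and \(\beta_{k0}\) are exactly confounded —
under a vague prior the posterior is a flat ridge that both destroys the
interpretability of \(\theta_{0k}\) and cripples the sampler. The fitting
formula therefore defaults to `study_length_term = "auto"`: the term is
estimated whenever study lengths vary and dropped when they are constant
(`"on"`/`"off"` force either behaviour). Internally the column is centred
and \(\theta_{0k}\) is mapped back to the uncentred parameterisation for
reporting, so reported parameters always refer to the link above.

## Priors and sampling

Vague priors follow the normal(0, 1000) convention for location-type
parameters and gamma(0.001, 0.001) for the frailty precision
\(\tau_k = 1/\sigma_k^2\). A normal prior on a positivity-constrained scale
or shape is ill-defined, so the normal(0, 1000) prior is applied to the
*unconstrained transform* — \(\log\theta_0\), \(\log\alpha\) for
Weibull/log-logistic, \(\alpha\) itself for Gompertz, and each \(\beta\) —
which is equally vague and keeps every draw in-domain. This divergence from
a truncated-normal reading is deliberate and documented here.

The sampler is an adaptive Metropolis-within-Gibbs scheme written for this
likelihood:

1. the top-level parameters update block-at-a-time — state-1, state-2 and
   dropout blocks, over which the likelihood factorises exactly — each by
   random-walk Metropolis with Haario-style covariance adaptation and
   Robbins–Monro step-size tuning during warmup; block updates mix far
   better than one joint proposal because a proposal is judged only by the
   rows it touches;
2. frailties update by vectorised per-subject Metropolis steps — they are
   conditionally independent given the top level, so all subjects propose
   and accept in parallel;
3. \(\sigma_k^2\) uses its conjugate gamma Gibbs update; and
4. a joint rescaling move proposes
   \((\eta_{k\cdot},\sigma_k^2)\to(\eta_{k\cdot}e^{\varepsilon/2},
   \sigma_k^2 e^{\varepsilon})\), whose Jacobian cancels the frailty prior
   exactly. This traverses the narrow funnel at small \(\sigma^2\) that
   the centred Gibbs scheme alone mixes through very slowly.

Chains run sequentially with seeds `seed + chain - 1`; identical seeds give
identical draws. Convergence is summarised by split-\(\hat R\) and an
autocorrelation-based effective sample size; \(\hat R > 1.05\) on a
top-level parameter records a warning on the fit rather than failing it.
Per-subject frailties are sampled, reported via their posterior means, and
excluded from the \(\hat R\) gate.

The deviance \(-2\log p(y\mid\theta,\eta)\) (conditional on the frailties,
excluding their prior) is stored at every kept draw, and
\(\mathrm{DIC} = \bar D + p_D\) with \(p_D = \bar D - D(\hat\theta)\), the
plug-in point being the posterior mean of the *unconstrained* parameters
and frailty means. DIC's sensitivity to the plug-in choice is known;
differences under 2 should be read as ties. Note also that this is the
*conditional* DIC (the deviance conditions on the sampled frailties, as in
the BUGS tradition): with only one or two sojourns per subject and
direction, a mis-specified family can buy conditional fit by inflating its
frailty variance and letting per-subject effects absorb the discrepancy,
and the \(p_D\) penalty does not fully repay it. Family comparisons should
therefore be read alongside the predictive checks, not on DIC alone.

## Dropout

Dropout is modelled as a separate time-to-event process (exponential,
Weibull or log-logistic — Gompertz is deliberately not offered) under a
missing-at-random assumption: dropout is independent of the unobserved
event process given covariates, so the joint likelihood factorises and the
dropout block can be fitted alone (`fit_dropout()`) or jointly
(`attach_dropout()`; joint refitting is the default, with the separate fit
available by simply not attaching). A subject is a *dropout* only when
follow-up ends more than a window (30 days by default, 14 for short
studies) before the nominal study end; later last visits count as complete,
censored at the observed end. Event-derived covariates (number of
exacerbations, total days in state 2) are computed from the observed
history and treated as fixed, exactly as a separate-fit analysis implies —
simulating dropout generatively from such covariates would break MAR, so
the replicate simulator omits dropout when they are present.

## The synthetic trial generator

No public COPD exacerbation trial data exist at the subject level, so the
package ships a generator whose defaults emulate the structure of 24–52
week exacerbation studies, and every downstream stage is exercised against
it. The reference scenario (`copd_trial_config()`) uses:

* 364-day follow-up; log-logistic sojourns with shapes 1.34 (onset) and
  2.97 (resolution) — values in the range reported for 52-week COPD trial
  fits;
* scale frailty variance 0.1 per direction;
* baseline scales \(\theta_1 = 150\), \(\theta_2 = 10\) days. The
  resolution scale gives mean exacerbation duration ≈ 12 days. The onset
  scale was calibrated *empirically* so a placebo subject has ≈ 1.5
  exacerbations per year, matching entry criteria of at least one
  exacerbation per year: with a heavy-tailed log-logistic (\(\alpha=1.34\))
  the long-run renewal mean is misleading at finite follow-up, so the
  scale was tuned on a large simulation rather than by the closed-form
  mean;
* covariate prevalences 0.5 (stage, smoking, season) and log-normal
  pack-years with median 40;
* optional sparse dropout: log-logistic with \(\theta_0=3500\),
  \(\alpha=1.5\) and a disease-stage coefficient of −0.68, calibrated to
  ≈ 5% observed dropout over 52 weeks.

Sojourns are drawn by inverse-CDF sampling and truncated at
\(\min(T_j, \text{dropout time})\); the final sojourn is censored. All
randomness flows through one mandatory seed; replicate simulations for
predictive checks use `seed + replicate_index`.

What the generator deliberately does **not** reproduce: seasonal
(time-varying) hazards, within-subject treatment switching, visit-schedule
artefacts, informative dropout, or correlated frailty across directions.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under the stated data-generating process, not fit to any
real trial.

### Numerical conventions

* **0.5-day resolution floor.** Source trials record events at day
  resolution, and \(\log h(t)\to\pm\infty\) as \(t\to0\) for some
  families. Durations below half a day are rejected by the data model;
  simulated draws are floored at 0.5 and a transition within half a day of
  end of follow-up is recorded as censoring. How same-day onset/resolution
  was recorded in the source trials is unstated; this floor is the
  package's convention.
* **Gompertz near zero shape.** \(S(t)=\exp\{(\theta/\alpha)(1-e^{\alpha
  t})\}\) is 0/0 at \(\alpha=0\); below \(|\alpha|<10^{-6}\) a series
  expansion is used, and the Weibull-at-1/Gompertz-at-0 reductions to the
  exponential are tested to \(10^{-6}\) or better.
* **Sampler-safe likelihood.** Out-of-domain parameter sets return
  \(-\infty\) from `total_loglik()` rather than raising, so any sampler
  can reject them.

## Diagnostics

`ppc()` draws parameter vectors from the posterior, simulates full trials
with the *observed* design (same subjects, covariates, study lengths —
parametric uncertainty only), and compares observed statistics — total
observation count, counts per state, mean exacerbations per subject,
dropout count — with the replicate distribution. `vpc()` bins completed
sojourn durations per state and overlays observed bin counts on the
replicates' 95% intervals, plus the per-subject exacerbation-count
distribution.

The number of VPC bins comes from one-dimensional k-means on the raw
(untransformed) durations with 10 restarts under a fixed seed, choosing
\(k\) at the elbow of the within-cluster sum of squares. The elbow is
automated as the largest second difference of the WSS curve — a package
decision, since visual elbow reading does not automate — with a manual
override (`k` argument). Bin boundaries are midpoints between adjacent
cluster centres, so bins partition the duration range.

## Drug effects and design exploration

`rate_ratio()` evaluates, per posterior draw, the hazard under reference
and alternative covariate settings and summarises
\(h_{\mathrm{ref}}(t)/h_{\mathrm{alt}}(t)\) pointwise; with placebo as
reference, a ratio above 1 on the onset direction means the drug delays
exacerbations. `transition_probability()` gives \(F(t)=1-S(t)\) for a
covariate stratum; we read the published "transition probability" as this
sojourn-level quantity rather than a state-occupancy probability (the
figures in question are per-transition curves) and note the ambiguity.
Curves are *typical-subject* curves: frailty is set to its median (0 on the
log scale) rather than integrated out — an option deliberately left simple
since population-averaged curves were not clearly intended — and the study
length is held at the design length on both sides so the \(\beta_{k0}\)
term cancels from ratios.

`design_experiment()` subsamples subjects without replacement or truncates
follow-up (re-censoring sojourns that cross the cut), refits, and reports
whether the 95% band of the rate ratio excludes 1 anywhere on the grid.
`extrapolate()` simulates from a short-study posterior out to a longer
horizon and compares the exacerbation-count distribution against the
full-length data; its `interval_width` attribute (the 95% predictive
interval of the mean count) quantifies how uncertainty grows with the
extrapolation horizon.

## Problem sizes used by the test suite

Parameter-recovery checks run at the reference conditions (150 subjects
per arm, 364 days; 600 subjects for the dropout model at ≈ 5% dropout;
300 subjects for family comparison). Where a check repeats over many
seeds, chains are shortened (2 chains, 400–800 kept draws after equal
warmup) relative to the single full-length fits (4 chains, ≥ 1000 kept
draws) so the suite completes comfortably on one CPU; the rescaling move
described above is what keeps short chains honest. Distributional checks
(Kolmogorov–Smirnov against the family CDFs) use ≥ 2000 completed
sojourns under long follow-up so censoring is negligible.

## Known limitations

* Per-direction families are uniform by default (`family2` allows mixing,
  e.g. Weibull onset with log-logistic resolution, but this path is not
  exercised by the reference scenario).
* Correlated (multivariate-normal) frailty across directions is not
  implemented — it was found unsupported in the motivating analyses — and
  would be the natural extension hook.
* DIC is the only model-comparison criterion; WAIC/LOO would require
  pointwise likelihood storage and are left as extensions.
* The dropout model cannot be made informative (MNAR); the MAR assumption
  is structural.
* Time-varying covariates (e.g. season during the trial) are out of scope.
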