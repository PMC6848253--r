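Package: copdsemi
Title: Bayesian Two-State Semi-Markov Models of COPD Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the onset and resolution of chronic obstructive pulmonary
    disease (COPD) exacerbations as an alternating two-state semi-Markov
    renewal process. Sojourn times in the asymptomatic and symptomatic states
    follow one of four parametric families (exponential, Weibull, Gompertz,
    log-logistic) with covariate effects and log-normal subject frailty on the
    scale parameter, fitted by Markov chain Monte Carlo under vague priors
    with a censoring-aware likelihood and deviance information criterion
    (DIC) model comparison. Includes a parametric time-to-dropout submodel,
    posterior and visual predictive checks with k-means duration binning,
    transition-rate-ratio and transition-probability drug-effect summaries,
    clinical trial design exploration (subsampling, follow-up truncation,
    extrapolation), and a synthetic trial generator that emulates 24-52 week
    COPD exacerbation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival
Config/testthat/edition: 3
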