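#' Simulation configuration for synthetic COPD exacerbation trials
#'
#' Defines one synthetic trial: arm sizes, follow-up, the two transition
#' specs (onset 1 to 2 and resolution 2 to 1), covariate generation settings
#' and an optional parametric dropout process. The generator reproduces the
#' structure of 24-52 week placebo-controlled COPD exacerbation studies:
#' alternating asymptomatic/symptomatic sojourns per subject with log-normal
#' scale frailty, binary covariates (treatment arm, disease stage, smoking,
#' season), continuous pack-years, administrative censoring at study end and
#' sparse independent dropout.
#'
#' @param n_per_arm Subjects per arm (two arms when \code{two_arms = TRUE},
#'   one placebo arm otherwise).
#' @param study_length Follow-up in days (single value applied to every
#'   subject, or a vector recycled across subjects).
#' @param spec1,spec2 [transition_spec()] for the 1 to 2 (onset) and 2 to 1
#'   (resolution) directions.
#' @param covariates List of generator settings: \code{stage_prev},
#'   \code{smoke_prev}, \code{season_prev} (Bernoulli prevalences) and
#'   \code{pack_years} = \code{c(meanlog, sdlog)} of a log-normal.
#' @param dropout \code{NULL} (no dropout) or a list with elements
#'   \code{family} (exponential/weibull/loglogistic), \code{theta0},
#'   \code{alpha}, \code{beta} (named coefficients on \code{disease_stage}
#'   etc.), giving the time-to-dropout distribution; drawn independently of
#'   the event process (missing-at-random).
#' @param dropout_window Days before nominal study end defining a dropout
#'   (default 30).
#' @param two_arms If \code{TRUE}, simulate an active arm
#'   (\code{treatment = 1}) alongside placebo.
#' @param seed Mandatory integer seed; all draws flow through it.
#'
#' @return An object of class \code{"simulation_config"}.
#' @seealso [copd_trial_config()] for the calibrated default scenario.
#' @export
simulation_config <- function(n_per_arm, study_length, spec1, spec2,
                              covariates = list(stage_prev = 0.5,
                                                smoke_prev = 0.5,
                                                season_prev = 0.5,
                                                pack_years = c(3.7, 0.4)),
                              dropout = NULL, dropout_window = 30,
                              two_arms = TRUE, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("`seed` is mandatory (no silent nondeterminism)", call. = FALSE)
  if (n_per_arm < 1) stop("`n_per_arm` must be >= 1", call. = FALSE)
  if (any(study_length <= 0)) stop("`study_length` must be > 0", call. = FALSE)
  stopifnot(inherits(spec1, "transition_spec"),
            inherits(spec2, "transition_spec"))
  if (!is.null(dropout)) {
    fam <- match_family(dropout$family)
    if (fam == "gompertz")
      stop("dropout family must be exponential, weibull or loglogistic",
           call. = FALSE)
    dropout$family <- fam
    if (is.null(dropout$beta)) dropout$beta <- numeric(0)
  }
  structure(list(n_per_arm = as.integer(n_per_arm),
                 study_length = study_length, spec1 = spec1, spec2 = spec2,
                 covariates = covariates, dropout = dropout,
                 dropout_window = dropout_window, two_arms = isTRUE(two_arms),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default synthetic scenario: a 52-week COPD exacerbation trial
#'
#' Ships the package's calibrated reference scenario: 52-week follow-up,
#' log-logistic sojourns in both directions with shapes 1.34 (onset) and 2.97
#' (resolution), scale frailty variance 0.1, and baseline scales
#' (\eqn{\theta_1 = 150}, \eqn{\theta_2 = 10} days) chosen so a typical
#' placebo subject has about 1.5 exacerbations per year lasting about 12
#' days each, consistent with trial populations enrolled at a history of at
#' least one exacerbation per year. Optional treatment and disease-stage
#' effects enter the onset scale on the log-linear link: a positive
#' \code{treatment_beta1} lengthens asymptomatic sojourns in the active arm
#' (placebo/active rate ratio above 1) and a negative \code{stage_beta1}
#' shortens them for moderate-or-worse disease.
#'
#' @param n_per_arm,seed,study_length,two_arms,dropout_window As in
#'   [simulation_config()].
#' @param treatment_beta1 Treatment coefficient on the onset (1 to 2) scale.
#' @param stage_beta1 Disease-stage coefficient on the onset scale.
#' @param sigma2 Frailty variance used for both directions.
#' @param family Sojourn family for both directions.
#' @param alpha1,alpha2,theta1,theta2 Shape/scale per direction.
#' @param dropout If \code{TRUE}, attach the default sparse log-logistic
#'   dropout process (about 5 percent dropout, disease-stage coefficient -0.68).
#' @return A [simulation_config()].
#' @export
copd_trial_config <- function(n_per_arm = 150, seed, study_length = 364,
                              family = "loglogistic",
                              alpha1 = 1.34, alpha2 = 2.97,
                              theta1 = 150, theta2 = 10,
                              treatment_beta1 = 0, stage_beta1 = 0,
                              sigma2 = 0.1, dropout = FALSE,
                              two_arms = treatment_beta1 != 0,
                              dropout_window = 30) {
  beta1 <- c(treatment = treatment_beta1, disease_stage = stage_beta1)
  beta1 <- beta1[beta1 != 0]
  use_alpha <- family != "exponential"
  simulation_config(
    n_per_arm = n_per_arm, study_length = study_length,
    spec1 = transition_spec(family, theta1,
                            alpha = if (use_alpha) alpha1, beta = beta1,
                            sigma2 = sigma2),
    spec2 = transition_spec(family, theta2,
                            alpha = if (use_alpha) alpha2, sigma2 = sigma2),
    dropout = if (isTRUE(dropout))
      list(family = "loglogistic", theta0 = 3500, alpha = 1.5,
           beta = c(disease_stage = -0.68)),
    dropout_window = dropout_window, two_arms = two_arms, seed = seed)
}

# duration resolution floor (days); see trial_dataset() validity rules
.min_sojourn <- 0.5

#' Simulate one subject's alternating sojourn history
#'
#' Starting in state 1 at time 0, repeatedly draws sojourn times by
#' inverse-CDF sampling from the frailty-and-covariate-adjusted family,
#' alternating states; the renewal clock resets at every transition
#' (semi-Markov). The final sojourn is truncated and censored at end of
#' follow-up. Drawn durations are floored at 0.5 days, and a transition
#' falling within 0.5 days of end of follow-up is recorded as censoring
#' (day-resolution convention).
#'
#' @param params1,params2 Lists with \code{theta}, \code{alpha} for the
#'   subject (after [link_subject_params()]).
#' @param family1,family2 Family names per direction.
#' @param followup End of observation in days (min of study length and
#'   dropout time).
#' @param subject_id Identifier for the returned records.
#' @return Data frame of sojourn records.
#' @keywords internal
simulate_subject <- function(params1, params2, family1, family2, followup,
                             subject_id = "s1") {
  state <- integer(0); duration <- numeric(0); event <- logical(0)
  t0 <- 0
  s <- 1L
  repeat {
    p <- if (s == 1L) params1 else params2
    fam <- if (s == 1L) family1 else family2
    d <- sojourn_quantile(fam, stats::runif(1), p$theta, p$alpha)
    d <- max(d, .min_sojourn)
    if (t0 + d >= followup - .min_sojourn) {
      state <- c(state, s)
      duration <- c(duration, followup - t0)
      event <- c(event, FALSE)
      break
    }
    state <- c(state, s); duration <- c(duration, d); event <- c(event, TRUE)
    t0 <- t0 + d
    s <- 3L - s
  }
  data.frame(subject_id = subject_id, episode = seq_along(state),
             state = state, duration = duration, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic trial
#'
#' Draws covariates, per-subject frailties, dropout times (when configured)
#' and alternating sojourn histories for every subject, and assembles a
#' validated [trial_dataset()]. Dropout is drawn independently of the event
#' process (missing at random) and acts as a competing truncation of
#' follow-up; the dropout flag follows the window rule. With the same seed
#' and configuration the result is identical.
#'
#' @param config A [simulation_config()].
#' @return A [trial_dataset()].
#' @examples
#' trial <- simulate_trial(copd_trial_config(n_per_arm = 20, seed = 1))
#' trial
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_arm <- config$n_per_arm
  n <- if (config$two_arms) 2L * n_arm else n_arm
  cv <- config$covariates
  subjects <- data.frame(
    subject_id = sprintf("s%04d", seq_len(n)),
    treatment = if (config$two_arms) rep(c(0L, 1L), each = n_arm)
                else rep(0L, n),
    disease_stage = stats::rbinom(n, 1, cv$stage_prev),
    smoke = stats::rbinom(n, 1, cv$smoke_prev),
    pack_years = round(stats::rlnorm(n, cv$pack_years[1], cv$pack_years[2]), 1),
    season = stats::rbinom(n, 1, cv$season_prev),
    study_length = rep_len(config$study_length, n),
    dropout_time = NA_real_, dropout_flag = FALSE,
    stringsAsFactors = FALSE)
  simulate_with_subjects(subjects, config$spec1, config$spec2,
                         dropout = config$dropout,
                         dropout_window = config$dropout_window)
}

#' Simulate sojourn histories for a fixed subject table
#'
#' Design-matched simulation: reuses the given subjects (ids, covariates,
#' study lengths) verbatim and draws frailties, dropout and event histories.
#' This is the engine behind [simulate_trial()] and the replicate simulator
#' for posterior and visual predictive checks.
#'
#' @param subjects Subject table as in [trial_dataset()] (dropout columns are
#'   overwritten).
#' @param spec1,spec2 [transition_spec()] per direction.
#' @param dropout \code{NULL} or a dropout spec list (\code{family},
#'   \code{theta0}, \code{alpha}, \code{beta}).
#' @param dropout_window Window in days for the dropout flag rule.
#' @param seed Optional; when supplied the RNG is seeded, otherwise the
#'   current RNG stream is used.
#' @return A [trial_dataset()].
#' @export
simulate_with_subjects <- function(subjects, spec1, spec2, dropout = NULL,
                                   dropout_window = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(subjects)
  subjects$dropout_time <- NA_real_
  subjects$dropout_flag <- FALSE

  # independent dropout times (MAR)
  if (!is.null(dropout)) {
    lp <- rep(0, n)
    for (nm in names(dropout$beta)) {
      x <- if (nm == "log_study_length") log(subjects$study_length)
           else subjects[[nm]]
      lp <- lp + dropout$beta[[nm]] * x
    }
    td <- sojourn_quantile(dropout$family, stats::runif(n),
                           dropout$theta0 * exp(lp), dropout$alpha)
    td <- pmax(td, 1)
    drop_obs <- td < subjects$study_length
    subjects$dropout_time[drop_obs] <- td[drop_obs]
  }

  eta1 <- stats::rnorm(n, 0, sqrt(spec1$sigma2))
  eta2 <- stats::rnorm(n, 0, sqrt(spec2$sigma2))

  soj <- vector("list", n)
  for (j in seq_len(n)) {
    covj <- subjects[j, ]
    p1 <- link_subject_params(spec1, covj, eta1[j])
    p2 <- link_subject_params(spec2, covj, eta2[j])
    fu <- min(covj$study_length, covj$dropout_time, na.rm = TRUE)
    soj[[j]] <- simulate_subject(p1, p2, spec1$family, spec2$family, fu,
                                 subjects$subject_id[j])
  }
  soj <- do.call(rbind, soj)
  fu_end <- tapply(soj$duration, soj$subject_id, sum)[subjects$subject_id]
  subjects$dropout_flag <-
    as.vector(fu_end < subjects$study_length - dropout_window - 1e-9)
  trial_dataset(subjects, soj, dropout_window = dropout_window)
}
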