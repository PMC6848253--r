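#' Transition-rate ratio between two covariate settings
#'
#' For every posterior draw, evaluates the hazard of the chosen transition
#' direction under a reference and an alternative covariate setting (frailty
#' at its median, 0 on the log scale; study length held at the design length
#' so the study-length term cancels) and forms the pointwise ratio
#' \eqn{h_{ref}(t) / h_{alt}(t)} over a time grid. With reference = placebo
#' and alternative = active arm, a ratio above 1 on the onset (1 to 2)
#' direction means the drug delays exacerbation onset.
#'
#' @param fit A [fit_two_state()] result.
#' @param direction 1 (onset, 1 to 2) or 2 (resolution, 2 to 1).
#' @param reference,alternative Named lists of covariate values (e.g.
#'   \code{list(treatment = 0)}); covariates not named default to 0. Any
#'   covariate on which the two settings differ must be in the fitted
#'   formula for that direction.
#' @param times Time grid in days; defaults to 1-day steps over (0, design
#'   study length].
#' @return A \code{rate_ratio_curve}: data frame \code{time},
#'   \code{median}, \code{lo}, \code{hi} (2.5/97.5 posterior percentiles).
#' @export
rate_ratio <- function(fit, direction = 1, reference = list(treatment = 0),
                       alternative = list(treatment = 1), times = NULL) {
  stopifnot(inherits(fit, "copd_fit"), direction %in% 1:2)
  check_contrast(fit, direction, reference, alternative)
  if (is.null(times))
    times <- seq_len(round(stats::median(fit$subjects$study_length)))
  hmat_ref <- contrast_hazard(fit, direction, reference, times)
  hmat_alt <- contrast_hazard(fit, direction, alternative, times)
  ratio <- hmat_ref / hmat_alt
  out <- data.frame(time = times,
                    median = apply(ratio, 2, stats::median),
                    lo = apply(ratio, 2, stats::quantile, 0.025),
                    hi = apply(ratio, 2, stats::quantile, 0.975))
  structure(out, class = c("rate_ratio_curve", "data.frame"),
            direction = direction)
}

check_contrast <- function(fit, direction, reference, alternative) {
  covs <- union(names(reference), names(alternative))
  differ <- covs[vapply(covs, function(nm) {
    r <- reference[[nm]]; a <- alternative[[nm]]
    !identical(ifelse(is.null(r), 0, r), ifelse(is.null(a), 0, a))
  }, TRUE)]
  absent <- setdiff(differ, fit$formula$covariates[[direction]])
  if (length(absent))
    stop("contrasted covariate(s) not in the fitted formula for direction ",
         direction, ": ", paste(absent, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# draws x times matrix of hazards under one covariate setting
contrast_hazard <- function(fit, direction, covariates, times,
                            what = c("hazard", "cdf")) {
  what <- match.arg(what)
  d <- fit$draws
  f <- fit$formula
  fam <- f$family[direction]
  T_design <- stats::median(fit$subjects$study_length)
  lp <- 0
  if (fit$sl_term)
    lp <- lp + d[[sprintf("beta_%d_log_study_length", direction)]] *
      log(T_design)
  for (nm in f$covariates[[direction]]) {
    x <- covariates[[nm]]
    if (is.null(x)) x <- 0
    lp <- lp + d[[sprintf("beta_%d_%s", direction, nm)]] * x
  }
  theta <- d[[sprintf("theta0_%d", direction)]] * exp(lp)
  alpha <- if (fam != "exponential") d[[sprintf("alpha_%d", direction)]]
  out <- matrix(NA_real_, nrow(d), length(times))
  lth <- log(theta)
  for (j in seq_along(times)) {
    t <- times[j]
    out[, j] <- if (what == "hazard")
      exp(log_hazard_kernel(fam, t, log(t), lth, alpha))
    else
      1 - exp(log_survival_kernel(fam, t, log(t), lth, alpha))
  }
  out
}

#' Transition probability curve for a covariate stratum
#'
#' Per posterior draw, the cumulative transition probability
#' \eqn{F(t) = 1 - S(t)} of having left the current state by sojourn time
#' \eqn{t} under the stratum's covariates (typical subject: frailty at 0),
#' summarised pointwise by the posterior median and 95% interval. Used to
#' compare, for example, placebo versus active arm within disease-stage
#' strata.
#'
#' @inheritParams rate_ratio
#' @param covariates Named list of the stratum's covariate values.
#' @param label Optional stratum label stored on the result.
#' @return A \code{transition_prob_curve}: data frame \code{time},
#'   \code{median}, \code{lo}, \code{hi}.
#' @export
transition_probability <- function(fit, direction = 1, covariates = list(),
                                   times = NULL, label = NULL) {
  stopifnot(inherits(fit, "copd_fit"), direction %in% 1:2)
  check_contrast(fit, direction, covariates, covariates)
  absent <- setdiff(names(covariates), fit$formula$covariates[[direction]])
  if (length(absent))
    stop("covariate(s) not in the fitted formula for direction ",
         direction, ": ", paste(absent, collapse = ", "), call. = FALSE)
  if (is.null(times))
    times <- seq_len(round(stats::median(fit$subjects$study_length)))
  cdf <- contrast_hazard(fit, direction, covariates, times, what = "cdf")
  out <- data.frame(time = times,
                    median = apply(cdf, 2, stats::median),
                    lo = apply(cdf, 2, stats::quantile, 0.025),
                    hi = apply(cdf, 2, stats::quantile, 0.975))
  structure(out, class = c("transition_prob_curve", "data.frame"),
            direction = direction, label = label)
}

#' @export
plot.rate_ratio_curve <- function(x, ...) {
  graphics::plot(x$time, x$median, type = "l", ylim = range(x$lo, x$hi, 1),
                 xlab = "time in state (days)", ylab = "transition rate ratio",
                 ...)
  graphics::lines(x$time, x$lo, lty = 2)
  graphics::lines(x$time, x$hi, lty = 2)
  graphics::abline(h = 1, col = "grey60")
  invisible(x)
}

#' @export
plot.transition_prob_curve <- function(x, ...) {
  graphics::plot(x$time, x$median, type = "l", ylim = c(0, 1),
                 xlab = "time in state (days)",
                 ylab = "transition probability 1 - S(t)", ...)
  graphics::lines(x$time, x$lo, lty = 2)
  graphics::lines(x$time, x$hi, lty = 2)
  invisible(x)
}
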