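#' Parametric sojourn-time families
#'
#' The two-state model describes COPD exacerbation histories as an alternating
#' renewal process: subjects move between an asymptomatic state (state 1) and
#' a symptomatic, exacerbated state (state 2), and the clock restarts at every
#' transition. The time spent in a state before transitioning (the sojourn
#' time) follows one of four parametric families, each defined by a hazard
#' \eqn{h(t)} and survival \eqn{S(t) = \exp(-\int_0^t h(u)\,du)}:
#'
#' \describe{
#'   \item{exponential}{\eqn{h(t) = \theta}; constant transition rate
#'     (first-order Markov).}
#'   \item{weibull}{\eqn{h(t) = \theta\alpha t^{\alpha-1}},
#'     \eqn{S(t) = \exp(-\theta t^{\alpha})}; \eqn{\log h} linear in
#'     \eqn{\log t}. Note \eqn{\theta} multiplies \eqn{t^\alpha} directly
#'     (a rate-like scale), not the accelerated-failure-time scale used by
#'     some other packages.}
#'   \item{gompertz}{\eqn{h(t) = \theta e^{\alpha t}},
#'     \eqn{S(t) = \exp\{(\theta/\alpha)(1 - e^{\alpha t})\}}; \eqn{\log h}
#'     linear in \eqn{t}. The shape \eqn{\alpha} may be negative, in which
#'     case the hazard decays and a fraction \eqn{\exp(\theta/\alpha)} of
#'     subjects never transition (the quantile function returns \code{Inf}
#'     beyond that mass and simulated sojourns are censored).}
#'   \item{loglogistic}{\eqn{h(t) = \alpha(t/\theta)^{\alpha}/
#'     [t\{1+(t/\theta)^{\alpha}\}]}, \eqn{S(t) = 1/\{1+(t/\theta)^{\alpha}\}};
#'     the logit of survival is linear in \eqn{\log t}, giving a
#'     rise-then-fall (bell-shaped) transition rate for \eqn{\alpha > 1}.}
#' }
#'
#' Time is measured in days throughout the package; \code{theta} carries the
#' family-specific per-day scale dimension and must be positive. \code{alpha}
#' must be positive for the Weibull and log-logistic families, is unrestricted
#' for the Gompertz family, and is ignored for the exponential family.
#'
#' @param family One of \code{"exponential"}, \code{"weibull"},
#'   \code{"gompertz"}, \code{"loglogistic"}.
#' @param t Sojourn time(s) in days; strictly positive for \code{hazard} and
#'   \code{sojourn_density}, non-negative for \code{survival}.
#' @param theta Scale parameter, \eqn{> 0}. Vectorised (recycled against
#'   \code{t}).
#' @param alpha Shape parameter (scalar); see family domains above.
#' @param u Probability in (0, 1) for \code{sojourn_quantile}.
#'
#' @return \code{hazard}: the instantaneous transition rate per day;
#'   \code{survival}: \eqn{S(t) \in (0, 1]}; \code{sojourn_density}:
#'   \eqn{f(t) = h(t) S(t)}; \code{sojourn_quantile}: the time \eqn{t} with
#'   \eqn{1 - S(t) = u} (possibly \code{Inf} for Gompertz with negative
#'   shape).
#'
#' @examples
#' hazard("exponential", t = 5, theta = 0.5)
#' survival("loglogistic", t = 10, theta = 10, alpha = 2)  # 0.5 at t = theta
#' sojourn_quantile("weibull", u = 0.5, theta = 0.01, alpha = 2)
#' @name families
NULL

sojourn_families <- c("exponential", "weibull", "gompertz", "loglogistic")

match_family <- function(family) {
  if (!is.character(family) || length(family) != 1L || is.na(family))
    stop("`family` must be a single character string", call. = FALSE)
  i <- pmatch(tolower(family), sojourn_families)
  if (is.na(i))
    stop("unknown family '", family, "'; must be one of ",
         paste(sojourn_families, collapse = ", "), call. = FALSE)
  sojourn_families[i]
}

check_family_args <- function(family, theta, alpha) {
  if (length(theta) == 0L || any(!is.finite(theta)) || any(theta <= 0))
    stop("`theta` must be finite and > 0", call. = FALSE)
  if (family != "exponential") {
    if (is.null(alpha) || length(alpha) != 1L || !is.finite(alpha))
      stop("`alpha` must be a single finite number for family '", family, "'",
           call. = FALSE)
    if (family %in% c("weibull", "loglogistic") && alpha <= 0)
      stop("`alpha` must be > 0 for family '", family, "'", call. = FALSE)
  }
  invisible(TRUE)
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# log h(t) with theta supplied on the log scale (vectorised over t,
# log_theta and alpha); the sampler-facing kernel shared by every public
# function.
log_hazard_kernel <- function(family, t, log_t, log_theta, alpha) {
  switch(family,
    exponential = log_theta + 0 * t,
    weibull     = log_theta + log(alpha) + (alpha - 1) * log_t,
    gompertz    = log_theta + alpha * t,
    loglogistic = {
      z <- alpha * (log_t - log_theta)
      log(alpha) + z - log_t - log1pexp(z)
    })
}

# log S(t); gompertz uses -(theta/alpha) * expm1(alpha t) with a series
# fallback near alpha = 0 to avoid 0/0.
log_survival_kernel <- function(family, t, log_t, log_theta, alpha) {
  switch(family,
    exponential = -exp(log_theta) * t,
    weibull     = -exp(log_theta + alpha * log_t),
    gompertz    = {
      len <- max(length(t), length(log_theta), length(alpha))
      t <- rep_len(t, len)
      theta <- rep_len(exp(log_theta), len)
      a <- rep_len(alpha, len)
      small <- abs(a) < 1e-6
      out <- numeric(len)
      if (any(!small))
        out[!small] <- -(theta[!small] / a[!small]) * expm1(a[!small] *
                                                            t[!small])
      if (any(small)) {
        at <- a[small] * t[small]
        out[small] <- -theta[small] * t[small] * (1 + at / 2 + at^2 / 6)
      }
      out
    },
    loglogistic = -log1pexp(alpha * (log_t - log_theta)))
}

#' @rdname families
#' @export
hazard <- function(family, t, theta, alpha = NULL) {
  family <- match_family(family)
  check_family_args(family, theta, alpha)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be finite and > 0", call. = FALSE)
  exp(log_hazard_kernel(family, t, log(t), log(theta), alpha))
}

#' @rdname families
#' @export
survival <- function(family, t, theta, alpha = NULL) {
  family <- match_family(family)
  check_family_args(family, theta, alpha)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  out <- numeric(length(t))
  pos <- t > 0
  out[!pos] <- 1
  if (any(pos)) {
    th <- rep_len(log(theta), length(t))
    out[pos] <- exp(log_survival_kernel(family, t[pos], log(t[pos]),
                                        th[pos], alpha))
  }
  out
}

#' @rdname families
#' @export
sojourn_density <- function(family, t, theta, alpha = NULL) {
  hazard(family, t, theta, alpha) * survival(family, t, theta, alpha)
}

#' @rdname families
#' @export
sojourn_quantile <- function(family, u, theta, alpha = NULL) {
  family <- match_family(family)
  check_family_args(family, theta, alpha)
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("`u` must lie strictly inside (0, 1)", call. = FALSE)
  l <- log1p(-u)  # log(1 - u) < 0
  switch(family,
    exponential = -l / theta,
    weibull     = (-l / theta)^(1 / alpha),
    gompertz    = {
      if (abs(alpha) < 1e-10) {
        -l / theta
      } else {
        arg <- 1 - (alpha / theta) * l
        out <- rep(Inf, length(arg))
        ok <- arg > 0
        out[ok] <- log(arg[ok]) / alpha
        out
      }
    },
    loglogistic = theta * (u / (1 - u))^(1 / alpha))
}
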