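#' Transition specification and the covariate/frailty link
#'
#' A `transition_spec` collects everything that determines the sojourn-time
#' distribution for one transition direction (1 to 2 = exacerbation onset,
#' 2 to 1 = resolution): the parametric family, the baseline scale
#' \eqn{\theta_0}, the shape \eqn{\alpha}, covariate coefficients \eqn{\beta},
#' and the variance \eqn{\sigma^2} of the subject-level frailty \eqn{\eta}.
#'
#' The subject-specific scale follows the log-linear link
#' \deqn{\theta_j = \theta_0 \, e^{\eta_j} \,
#'       \exp\{\beta_0 \log T_j + \beta_1 X_{1j} + \dots + \beta_M X_{Mj}\}}
#' where \eqn{T_j} is subject \eqn{j}'s study length in days (its coefficient
#' is named \code{log_study_length}) and \eqn{\eta_j \sim N(0, \sigma^2)}. The
#' frailty enters as the log-normal multiplier \eqn{e^{\eta_j}} so that
#' \eqn{\theta_j > 0} always holds; see the methods vignette for why this
#' parameterisation was chosen, and note that by default the frailty acts on
#' the scale only (the shape stays fixed across subjects, with an optional
#' switch for shape frailty).
#'
#' @param family Sojourn-time family name; see [families].
#' @param theta0 Baseline scale, \eqn{> 0} (per-day rate dimension,
#'   family-specific).
#' @param alpha Shape parameter; \code{NULL} for the exponential family.
#' @param beta Named numeric vector of covariate coefficients. Allowed names:
#'   \code{log_study_length}, \code{treatment}, \code{disease_stage},
#'   \code{smoke}, \code{pack_years}, \code{season}.
#' @param sigma2 Frailty variance \eqn{\sigma^2 \ge 0}.
#' @param shape_frailty If \code{TRUE}, the frailty multiplier is also applied
#'   to the shape (\eqn{\alpha_j = \alpha e^{\eta_j}}); off by default.
#'
#' @return An object of class \code{"transition_spec"}.
#' @examples
#' sp <- transition_spec("loglogistic", theta0 = 70, alpha = 1.34,
#'                       beta = c(disease_stage = -0.40), sigma2 = 0.1)
#' link_subject_params(sp, list(disease_stage = 1, study_length = 364), eta = 0)
#' @export
transition_spec <- function(family, theta0, alpha = NULL, beta = numeric(0),
                            sigma2 = 0, shape_frailty = FALSE) {
  family <- match_family(family)
  check_family_args(family, theta0, alpha)
  if (length(theta0) != 1L)
    stop("`theta0` must be a single number", call. = FALSE)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 < 0)
    stop("`sigma2` must be a single finite number >= 0", call. = FALSE)
  if (length(beta)) {
    if (is.null(names(beta)) || any(!nzchar(names(beta))))
      stop("`beta` must be a named vector", call. = FALSE)
    bad <- setdiff(names(beta), c("log_study_length", subject_covariate_names))
    if (length(bad))
      stop("unknown covariate name(s) in `beta`: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(family = family, theta0 = theta0, alpha = alpha,
                 beta = beta, sigma2 = sigma2,
                 shape_frailty = isTRUE(shape_frailty)),
            class = "transition_spec")
}

subject_covariate_names <- c("treatment", "disease_stage", "smoke",
                             "pack_years", "season")

#' @export
print.transition_spec <- function(x, ...) {
  cat("Transition spec:", x$family,
      sprintf("theta0 = %g", x$theta0),
      if (!is.null(x$alpha)) sprintf("alpha = %g", x$alpha), "\n")
  if (length(x$beta))
    cat("  beta:", paste(names(x$beta), signif(x$beta, 4), sep = " = ",
                         collapse = ", "), "\n")
  cat("  frailty variance sigma2 =", x$sigma2,
      if (x$shape_frailty) "(on scale and shape)" else "(scale only)", "\n")
  invisible(x)
}

#' @rdname transition_spec
#' @param spec A \code{transition_spec}.
#' @param covariates Named list or one-row data frame holding the subject's
#'   covariates; must contain \code{study_length} (days) plus every covariate
#'   named in \code{spec$beta}.
#' @param eta Subject frailty draw on the log scale (0 = typical subject).
#' @export
link_subject_params <- function(spec, covariates, eta = 0) {
  stopifnot(inherits(spec, "transition_spec"))
  covariates <- as.list(covariates)
  if (is.null(covariates$study_length) || covariates$study_length <= 0)
    stop("`covariates` must contain a positive `study_length`", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta))
    stop("`eta` must be a single finite number", call. = FALSE)
  lp <- 0
  for (nm in names(spec$beta)) {
    x <- if (nm == "log_study_length") log(covariates$study_length)
         else covariates[[nm]]
    if (is.null(x))
      stop("covariate '", nm, "' required by the transition spec is missing",
           call. = FALSE)
    lp <- lp + spec$beta[[nm]] * x
  }
  theta <- spec$theta0 * exp(eta) * exp(lp)
  alpha <- spec$alpha
  if (spec$shape_frailty && !is.null(alpha)) alpha <- alpha * exp(eta)
  list(theta = theta, alpha = alpha)
}
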