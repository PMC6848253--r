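#' Censoring-aware log-likelihood of sojourn records
#'
#' Each observed interval contributes \eqn{\log h(t) + \log S(t)} when the
#' transition out of the state was observed (\code{event = TRUE}, density
#' contribution \eqn{f = h S}) and \eqn{\log S(t)} when the interval was
#' right-censored at end of follow-up.
#'
#' @param duration Sojourn duration(s) in days, \eqn{> 0}.
#' @param event Logical; \code{TRUE} when the transition was observed.
#' @param family Sojourn family; see [families].
#' @param theta Subject-level scale(s) (recycled against \code{duration}).
#' @param alpha Shape (scalar).
#' @return Vector of per-record log-likelihood contributions.
#' @examples
#' sojourn_loglik(2, TRUE, "exponential", theta = 0.5)   # log(0.5) - 1
#' @export
sojourn_loglik <- function(duration, event, family, theta, alpha = NULL) {
  family <- match_family(family)
  check_family_args(family, theta, alpha)
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("`duration` must be finite and > 0", call. = FALSE)
  event <- rep_len(as.logical(event), length(duration))
  lt <- log(duration)
  lth <- rep_len(log(theta), length(duration))
  ls <- log_survival_kernel(family, duration, lt, lth, alpha)
  ll <- ifelse(event, log_hazard_kernel(family, duration, lt, lth, alpha) + ls,
               ls)
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood at record ",
         which(!is.finite(ll))[1], call. = FALSE)
  ll
}

# --- internal likelihood engine -------------------------------------------

# Per-direction context: rows of one state plus the subject-level design
# matrix. `X` has one row per subject; `subj` maps sojourn rows to subjects.
direction_context <- function(dataset, state, covariates, sl_term,
                              center_sl = FALSE) {
  sub <- dataset$subjects
  soj <- dataset$sojourns[dataset$sojourns$state == state, , drop = FALSE]
  cols <- list()
  center <- 0
  if (sl_term) {
    lsl <- log(sub$study_length)
    if (center_sl) {
      center <- mean(lsl)
      lsl <- lsl - center
    }
    cols$log_study_length <- lsl
  }
  for (nm in covariates) cols[[nm]] <- sub[[nm]]
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(sub), 0)
  list(t = soj$duration, log_t = log(soj$duration), event = soj$event,
       subj = match(soj$subject_id, sub$subject_id),
       X = X, n_subjects = nrow(sub), n_rows = nrow(soj),
       sl_center = center)
}

# Row-level log-likelihood for one direction given unconstrained-scale
# inputs; eta is the per-subject frailty vector (0 when frailty is off).
direction_loglik_rows <- function(ctx, family, log_theta0, alpha, beta, eta) {
  if (ctx$n_rows == 0L) return(numeric(0))
  lp <- if (ncol(ctx$X)) as.vector(ctx$X %*% beta) else 0
  log_theta_sub <- log_theta0 + lp + eta
  lth <- log_theta_sub[ctx$subj]
  ls <- log_survival_kernel(family, ctx$t, ctx$log_t, lth, alpha)
  lh <- log_hazard_kernel(family, ctx$t, ctx$log_t, lth, alpha)
  ifelse(ctx$event, lh + ls, ls)
}

#' Total model log-likelihood at fixed parameters
#'
#' Sums the per-record censoring-aware contributions over both transition
#' directions using the covariate/frailty link, adds the frailty log-prior
#' \eqn{\sum_j \log N(\eta_{kj}; 0, \sigma_k^2)} for each direction with
#' frailty active, and adds the dropout submodel contributions when the
#' formula attaches one. Out-of-domain parameters return \code{-Inf} (the
#' sampler-safe contract) rather than raising.
#'
#' @param dataset A [trial_dataset()].
#' @param formula A [two_state_formula()].
#' @param params Named list with elements \code{dir1}, \code{dir2}, each a
#'   list of \code{theta0}, \code{alpha}, \code{beta} (named as in the
#'   formula, including \code{log_study_length} when that term is active),
#'   \code{sigma2} and \code{eta} (per-subject frailty vector, in
#'   \code{dataset$subjects} order); plus \code{dropout} (\code{theta0},
#'   \code{alpha}, \code{beta}) when the formula attaches dropout.
#' @return A single number (possibly \code{-Inf}).
#' @export
total_loglik <- function(dataset, formula, params) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(formula, "two_state_formula"))
  sl_on <- formula_sl_term(formula, dataset)
  total <- 0
  for (k in 1:2) {
    pk <- params[[paste0("dir", k)]]
    fam <- formula$family[k]
    if (pk$theta0 <= 0 || !is.finite(pk$theta0)) return(-Inf)
    if (fam != "exponential" &&
        (fam %in% c("weibull", "loglogistic")) && pk$alpha <= 0) return(-Inf)
    if (formula$frailty[k] && (is.null(pk$sigma2) || pk$sigma2 < 0))
      return(-Inf)
    ctx <- direction_context(dataset, k, formula$covariates[[k]], sl_on)
    eta <- if (formula$frailty[k] && !is.null(pk$eta)) pk$eta
           else rep(0, ctx$n_subjects)
    beta <- align_beta(pk$beta, colnames(ctx$X))
    ll <- direction_loglik_rows(ctx, fam, log(pk$theta0), pk$alpha, beta, eta)
    if (any(!is.finite(ll))) return(-Inf)
    total <- total + sum(ll)
    if (formula$frailty[k]) {
      if (pk$sigma2 == 0) {
        if (any(eta != 0)) return(-Inf)
      } else {
        total <- total + sum(stats::dnorm(eta, 0, sqrt(pk$sigma2), log = TRUE))
      }
    }
  }
  if (!is.null(formula$dropout)) {
    dctx <- dropout_context(dataset, formula$dropout, sl_on)
    pd <- params$dropout
    if (pd$theta0 <= 0) return(-Inf)
    ll <- direction_loglik_rows(dctx, formula$dropout$family, log(pd$theta0),
                                pd$alpha, align_beta(pd$beta, colnames(dctx$X)),
                                rep(0, dctx$n_subjects))
    if (any(!is.finite(ll))) return(-Inf)
    total <- total + sum(ll)
  }
  total
}

align_beta <- function(beta, cols) {
  if (!length(cols)) return(numeric(0))
  if (is.null(names(beta))) {
    if (length(beta) != length(cols))
      stop("beta length must match the model covariates (",
           paste(cols, collapse = ", "), ")", call. = FALSE)
    return(as.numeric(beta))
  }
  miss <- setdiff(cols, names(beta))
  if (length(miss))
    stop("beta is missing coefficient(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.numeric(beta[cols])
}
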