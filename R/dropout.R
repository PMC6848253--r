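#' Fit the parametric dropout model separately
#'
#' Fits the time-to-dropout model on dropout data alone: the event is
#' dropping out (follow-up ending more than the dropout window before the
#' nominal study end), subjects followed to the end are right-censored at
#' their observed end of follow-up, and event-derived covariates (number of
#' exacerbations, total days in state 2) are computed from the observed
#' histories and treated as fixed. Priors, sampler and DIC machinery match
#' [fit_two_state()].
#'
#' @param dataset A [trial_dataset()] carrying dropout outcomes.
#' @param formula A [dropout_formula()].
#' @param control A [sampler_control()].
#' @param prior A [prior_config()].
#' @return An object of class \code{"dropout_fit"} with the same shape as a
#'   \code{copd_fit} (draws, deviance trace, DIC, pD, summary).
#' @export
fit_dropout <- function(dataset, formula, control, prior = prior_config()) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(formula, "dropout_formula"),
            inherits(control, "sampler_control"))
  sl_on <- isTRUE(stats::var(log(dataset$subjects$study_length)) > 0)
  dctx <- dropout_context(dataset, formula, sl_on, center_sl = TRUE)
  if (!any(dctx$event))
    warning("no dropouts observed: dropout effects are unidentifiable",
            call. = FALSE)
  fam <- formula$family
  p_beta <- ncol(dctx$X)
  nm <- c("dropout_theta0",
          if (fam != "exponential") "dropout_alpha",
          if (p_beta) paste0("dropout_beta_", colnames(dctx$X)))
  p <- length(nm)

  loglik <- function(z) {
    alpha <- if (fam != "exponential") exp(z[2])
    beta <- if (p_beta) z[(p - p_beta + 1):p] else numeric(0)
    sum(direction_loglik_rows(dctx, fam, z[1], alpha, beta,
                              rep(0, dctx$n_subjects)))
  }

  chains <- lapply(seq_len(control$chains), function(ch) {
    set.seed(control$seed + ch - 1L)
    z <- c(init_direction(dctx, fam), numeric(p_beta)) +
      stats::rnorm(p, 0, 0.1)
    cur_ll <- loglik(z)
    if (!is.finite(cur_ll)) { z <- rep(-2, p); cur_ll <- loglik(z) }
    lp <- function(zv) sum(stats::dnorm(zv, 0, prior$coef_sd, log = TRUE))
    cur_lp <- lp(z)
    ls <- log(0.3 / sqrt(p))
    S1 <- numeric(p); S2 <- matrix(0, p, p); L <- diag(p)
    keep <- control$draws
    zmat <- matrix(NA_real_, keep, p)
    dev <- numeric(keep)
    for (it in seq_len(control$warmup + keep)) {
      zp <- z + exp(ls) * as.vector(L %*% stats::rnorm(p))
      new_ll <- loglik(zp)
      a <- if (is.finite(new_ll))
        exp(min(0, new_ll + lp(zp) - cur_ll - cur_lp)) else 0
      if (stats::runif(1) < a) { z <- zp; cur_ll <- new_ll; cur_lp <- lp(z) }
      if (it <= control$warmup) {
        ls <- ls + (a - control$adapt_target) / it^0.6
        S1 <- S1 + z; S2 <- S2 + tcrossprod(z)
        if (it >= 50 && it %% 25 == 0) {
          cv <- (S2 - tcrossprod(S1) / it) / (it - 1)
          ch2 <- tryCatch(chol(cv + diag(1e-8, p)), error = function(e) NULL)
          if (!is.null(ch2)) L <- t(ch2)
        }
      } else {
        zmat[it - control$warmup, ] <- z
        dev[it - control$warmup] <- -2 * cur_ll
      }
    }
    list(z = zmat, deviance = dev)
  })

  zdraws <- do.call(rbind, lapply(chains, `[[`, "z"))
  deviance <- unlist(lapply(chains, `[[`, "deviance"), use.names = FALSE)
  z_bar <- colMeans(zdraws)
  d_hat <- -2 * loglik(z_bar)
  d_bar <- mean(deviance)
  pd <- d_bar - d_hat
  # natural scale, theta0 transformed back to the uncentred parameterisation
  nat <- zdraws
  nat[, 1] <- zdraws[, 1]
  cn <- colnames(dctx$X)
  if (dctx$sl_center != 0 && "log_study_length" %in% cn) {
    b0 <- zdraws[, p - p_beta + match("log_study_length", cn)]
    nat[, 1] <- nat[, 1] - b0 * dctx$sl_center
  }
  nat[, 1] <- exp(nat[, 1])
  if (fam != "exponential") nat[, 2] <- exp(nat[, 2])
  colnames(nat) <- nm

  draws <- data.frame(chain = rep(seq_len(control$chains),
                                  each = control$draws),
                      iter = rep(seq_len(control$draws), control$chains))
  draws <- cbind(draws, as.data.frame(nat))
  summ <- summarize_draws(draws, nm, control$chains)
  warnings <- character(0)
  if (any(summ$rhat > 1.05, na.rm = TRUE)) {
    warnings <- paste0("split-Rhat > 1.05 for: ",
                       paste(summ$parameter[summ$rhat > 1.05],
                             collapse = ", "))
    warning(warnings, call. = FALSE)
  }
  structure(list(draws = draws, deviance = deviance, dic = d_bar + pd,
                 pd = pd, summary = summ, formula = formula,
                 control = control, prior = prior,
                 subjects = dataset$subjects,
                 dropout_window = dataset$dropout_window,
                 sl_term = sl_on, warnings = warnings),
            class = "dropout_fit")
}

#' @export
print.dropout_fit <- function(x, ...) {
  cat("Dropout time-to-event fit (", x$formula$family, "), ",
      sum(x$subjects$dropout_flag), "/", nrow(x$subjects),
      " dropouts, DIC ", round(x$dic, 1), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dropout_fit <- function(object, ...) object$summary
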