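#' Sampler and prior configuration
#'
#' The sampler is an adaptive Metropolis-within-Gibbs scheme: the top-level
#' parameters (log scales, shapes on their unconstrained transform, covariate
#' coefficients) are updated jointly by adaptive random-walk Metropolis with
#' covariance adaptation during warmup; per-subject frailties are updated by
#' vectorised independent Metropolis steps (they are conditionally
#' independent given the top-level block); and the frailty variance uses its
#' conjugate gamma Gibbs update. Adaptation stops at the end of warmup.
#'
#' @param chains Number of chains (run sequentially with seeds
#'   \code{seed + chain - 1}).
#' @param draws Post-warmup draws kept per chain.
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param seed Mandatory integer seed.
#' @param adapt_target Target acceptance rate of the top-level block.
#' @return A list of class \code{"sampler_control"}.
#' @export
sampler_control <- function(chains = 4, draws = 1000, warmup = 500, seed,
                            adapt_target = 0.234) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("`seed` is mandatory", call. = FALSE)
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 adapt_target = adapt_target),
            class = "sampler_control")
}

#' @rdname sampler_control
#' @param coef_sd Prior standard deviation of the vague normal prior applied
#'   to every unconstrained top-level parameter (scales and positive shapes on
#'   the log scale, Gompertz shapes and coefficients untransformed); the
#'   default \code{sqrt(1000)} mirrors a normal(0, 1000) vague prior.
#' @param tau_shape,tau_rate Gamma prior on the frailty precision
#'   \eqn{\tau = 1/\sigma^2}; defaults gamma(0.001, 0.001).
#' @export
prior_config <- function(coef_sd = sqrt(1000), tau_shape = 0.001,
                         tau_rate = 0.001) {
  structure(list(coef_sd = coef_sd, tau_shape = tau_shape,
                 tau_rate = tau_rate),
            class = "prior_config")
}

# --- parameter layout -----------------------------------------------------

# Describes the unconstrained top-level vector z: for each direction
# log(theta0), shape transform, beta coefficients; then the dropout block.
build_layout <- function(formula, ctx1, ctx2, dctx) {
  nm <- character(0); trans <- character(0); block <- character(0)
  add <- function(names, transforms, blk) {
    nm <<- c(nm, names); trans <<- c(trans, transforms)
    block <<- c(block, rep(blk, length(names)))
  }
  for (k in 1:2) {
    ctx <- if (k == 1) ctx1 else ctx2
    fam <- formula$family[k]
    add(sprintf("theta0_%d", k), "log", paste0("dir", k))
    if (fam != "exponential")
      add(sprintf("alpha_%d", k),
          if (fam == "gompertz") "identity" else "log", paste0("dir", k))
    if (ncol(ctx$X))
      add(sprintf("beta_%d_%s", k, colnames(ctx$X)),
          rep("identity", ncol(ctx$X)), paste0("dir", k))
  }
  if (!is.null(dctx)) {
    fam <- formula$dropout$family
    add("dropout_theta0", "log", "dropout")
    if (fam != "exponential")
      add("dropout_alpha", "log", "dropout")
    if (ncol(dctx$X))
      add(paste0("dropout_beta_", colnames(dctx$X)),
          rep("identity", ncol(dctx$X)), "dropout")
  }
  list(names = nm, trans = trans, block = block, p = length(nm))
}

# split z into the pieces the likelihood wants
unpack_z <- function(z, layout, formula, ctx1, ctx2, dctx) {
  out <- list()
  i <- 1L
  for (k in 1:2) {
    ctx <- if (k == 1) ctx1 else ctx2
    fam <- formula$family[k]
    lt0 <- z[i]; i <- i + 1L
    alpha <- NULL
    if (fam != "exponential") {
      alpha <- if (fam == "gompertz") z[i] else exp(z[i])
      i <- i + 1L
    }
    p <- ncol(ctx$X)
    beta <- if (p) z[i:(i + p - 1L)] else numeric(0)
    i <- i + p
    out[[paste0("dir", k)]] <- list(log_theta0 = lt0, alpha = alpha,
                                    beta = beta)
  }
  if (!is.null(dctx)) {
    fam <- formula$dropout$family
    lt0 <- z[i]; i <- i + 1L
    alpha <- NULL
    if (fam != "exponential") { alpha <- exp(z[i]); i <- i + 1L }
    p <- ncol(dctx$X)
    beta <- if (p) z[i:(i + p - 1L)] else numeric(0)
    out$dropout <- list(log_theta0 = lt0, alpha = alpha, beta = beta)
  }
  out
}

# crude data-driven starting values per direction
init_direction <- function(ctx, family) {
  if (ctx$n_rows == 0L || !any(ctx$event)) {
    lt0 <- log(0.01)
    comp <- 50
  } else {
    rate <- sum(ctx$event) / sum(ctx$t)
    comp <- stats::median(ctx$t[ctx$event])
    lt0 <- log(rate)
  }
  switch(family,
    exponential = lt0,
    weibull     = c(lt0, 0),
    gompertz    = c(lt0, 1e-4),
    loglogistic = c(log(comp), log(1.5)))
}

#' Fit the two-state semi-Markov model by MCMC
#'
#' Assembles the censoring-aware joint log-likelihood over both transition
#' directions (plus the dropout submodel when the formula attaches one),
#' applies vague priors — normal(0, 1000) on each unconstrained top-level
#' parameter and gamma(0.001, 0.001) on the frailty precision — and samples
#' the posterior. The deviance \eqn{-2 \log p(y \mid \theta, \eta)} is
#' recorded at every kept draw and the deviance information criterion is
#' computed as \eqn{DIC = \bar D + p_D} with
#' \eqn{p_D = \bar D - D(\hat\theta)}, the plug-in point being the posterior
#' mean of the unconstrained parameters and frailties.
#'
#' If any top-level parameter has split-\eqn{\hat R > 1.05} a warning is
#' recorded in the fit (and emitted), not an error.
#'
#' @param dataset A [trial_dataset()].
#' @param formula A [two_state_formula()].
#' @param control A [sampler_control()] (carries the seed).
#' @param prior A [prior_config()].
#' @return An object of class \code{"copd_fit"} with elements \code{draws}
#'   (data frame: chain, iter, one column per reported parameter),
#'   \code{deviance}, \code{dic}, \code{pd}, \code{summary} (median, 2.5 and
#'   97.5 percentiles, split-\eqn{\hat R}, effective sample size),
#'   \code{eta_mean}, \code{formula}, \code{control} and the subject table
#'   needed to re-simulate the design.
#' @examples
#' \donttest{
#' trial <- simulate_trial(copd_trial_config(n_per_arm = 40, seed = 1,
#'                                           family = "exponential",
#'                                           sigma2 = 0))
#' f <- two_state_formula("exponential", frailty1 = FALSE, frailty2 = FALSE)
#' fit <- fit_two_state(trial, f, sampler_control(chains = 2, draws = 300,
#'                                                warmup = 300, seed = 1))
#' summary(fit)
#' }
#' @export
fit_two_state <- function(dataset, formula, control,
                          prior = prior_config()) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(formula, "two_state_formula"),
            inherits(control, "sampler_control"))
  sl_on <- formula_sl_term(formula, dataset)
  ctx1 <- direction_context(dataset, 1, formula$covariates[[1]], sl_on,
                            center_sl = TRUE)
  ctx2 <- direction_context(dataset, 2, formula$covariates[[2]], sl_on,
                            center_sl = TRUE)
  dctx <- if (!is.null(formula$dropout))
    dropout_context(dataset, formula$dropout, sl_on, center_sl = TRUE)
  layout <- build_layout(formula, ctx1, ctx2, dctx)
  if (!is.null(dctx) && !any(dctx$event))
    warning("no dropouts observed: dropout effects are unidentifiable",
            call. = FALSE)

  chains <- lapply(seq_len(control$chains), function(ch)
    run_chain(formula, ctx1, ctx2, dctx, layout, prior, control,
              seed = control$seed + ch - 1L, chain_id = ch))

  draws_nat <- do.call(rbind, lapply(chains, `[[`, "nat"))
  draws_z <- do.call(rbind, lapply(chains, `[[`, "z"))
  deviance <- unlist(lapply(chains, `[[`, "deviance"), use.names = FALSE)
  chain_id <- rep(seq_len(control$chains), each = control$draws)

  # plug-in deviance at posterior means of unconstrained parameters/frailties
  z_bar <- colMeans(draws_z)
  eta1_bar <- Reduce(`+`, lapply(chains, `[[`, "eta1_mean")) / control$chains
  eta2_bar <- Reduce(`+`, lapply(chains, `[[`, "eta2_mean")) / control$chains
  d_hat <- -2 * data_loglik(z_bar, eta1_bar, eta2_bar, formula,
                            ctx1, ctx2, dctx, layout)
  d_bar <- mean(deviance)
  pd <- d_bar - d_hat
  dic <- d_bar + pd

  draws <- data.frame(chain = chain_id,
                      iter = rep(seq_len(control$draws), control$chains))
  draws <- cbind(draws, as.data.frame(draws_nat))

  par_cols <- setdiff(names(draws), c("chain", "iter"))
  summ <- summarize_draws(draws, par_cols, control$chains)
  warnings <- character(0)
  top <- !grepl("^sigma2_", par_cols)
  bad <- summ$rhat[match(par_cols[top], summ$parameter)] > 1.05
  if (any(bad, na.rm = TRUE)) {
    warnings <- paste0("split-Rhat > 1.05 for: ",
                       paste(par_cols[top][which(bad)], collapse = ", "))
    warning(warnings, call. = FALSE)
  }

  structure(list(draws = draws, deviance = deviance, dic = dic, pd = pd,
                 summary = summ, formula = formula, control = control,
                 prior = prior,
                 eta_mean = cbind(dir1 = eta1_bar, dir2 = eta2_bar),
                 subjects = dataset$subjects,
                 dropout_window = dataset$dropout_window,
                 sl_term = sl_on, sl_center = ctx1$sl_center,
                 warnings = warnings),
            class = "copd_fit")
}

# total data log-likelihood (excludes frailty prior): the deviance kernel
data_loglik <- function(z, eta1, eta2, formula, ctx1, ctx2, dctx, layout) {
  pz <- unpack_z(z, layout, formula, ctx1, ctx2, dctx)
  ll <- sum(direction_loglik_rows(ctx1, formula$family[1],
                                  pz$dir1$log_theta0, pz$dir1$alpha,
                                  pz$dir1$beta, eta1)) +
        sum(direction_loglik_rows(ctx2, formula$family[2],
                                  pz$dir2$log_theta0, pz$dir2$alpha,
                                  pz$dir2$beta, eta2))
  if (!is.null(dctx))
    ll <- ll + sum(direction_loglik_rows(dctx, formula$dropout$family,
                                         pz$dropout$log_theta0,
                                         pz$dropout$alpha, pz$dropout$beta,
                                         rep(0, dctx$n_subjects)))
  ll
}

run_chain <- function(formula, ctx1, ctx2, dctx, layout, prior, control,
                      seed, chain_id) {
  set.seed(seed)
  p <- layout$p
  n <- ctx1$n_subjects
  warmup <- control$warmup
  keep <- control$draws
  target <- control$adapt_target

  # initial state
  z <- numeric(p)
  i <- 1L
  for (k in 1:2) {
    ctx <- if (k == 1) ctx1 else ctx2
    ini <- init_direction(ctx, formula$family[k])
    z[i:(i + length(ini) - 1L)] <- ini
    i <- i + length(ini) + ncol(ctx$X)
  }
  if (!is.null(dctx)) {
    ini <- init_direction(dctx, formula$dropout$family)
    z[i:(i + length(ini) - 1L)] <- ini
  }
  z <- z + stats::rnorm(p, 0, 0.1)  # overdispersed starts

  eta1 <- numeric(n); eta2 <- numeric(n)
  sig <- c(0.1, 0.1)
  frail <- formula$frailty & n > 0

  # the likelihood factorises over blocks (state-1 rows, state-2 rows,
  # dropout rows), so the top level updates block-at-a-time: each adaptive
  # Metropolis proposal touches only its own rows, which mixes far better
  # than one joint proposal over all parameters
  blocks <- unique(layout$block)
  binfo <- lapply(blocks, function(b) {
    ctx <- switch(b, dir1 = ctx1, dir2 = ctx2, dropout = dctx)
    fam <- switch(b, dir1 = formula$family[1], dir2 = formula$family[2],
                  dropout = formula$dropout$family)
    list(name = b, idx = which(layout$block == b), ctx = ctx, fam = fam)
  })
  names(binfo) <- blocks

  block_ll <- function(b, zv) {
    pz <- unpack_z(zv, layout, formula, ctx1, ctx2, dctx)
    pk <- pz[[b$name]]
    eta <- switch(b$name, dir1 = eta1, dir2 = eta2,
                  dropout = rep(0, b$ctx$n_subjects))
    ll <- direction_loglik_rows(b$ctx, b$fam, pk$log_theta0,
                                pk$alpha, pk$beta, eta)
    ll[!is.finite(ll)] <- -Inf
    sum(ll)
  }

  llb <- vapply(binfo, function(b) block_ll(b, z), 0)
  if (any(!is.finite(llb))) {
    z <- rep(-2, p)
    llb <- vapply(binfo, function(b) block_ll(b, z), 0)
  }

  # adaptation state per block
  ad <- lapply(binfo, function(b) {
    pb <- length(b$idx)
    list(ls = log(0.4 / sqrt(pb)), S1 = numeric(pb),
         S2 = matrix(0, pb, pb), L = diag(pb))
  })
  ls_eta <- c(log(0.5), log(0.5))

  nat <- matrix(NA_real_, keep, length(layout$names) + sum(frail))
  zmat <- matrix(NA_real_, keep, p)
  dev <- numeric(keep)
  eta1_acc <- numeric(n); eta2_acc <- numeric(n)

  lps2 <- function(s2)
    stats::dgamma(1 / s2, prior$tau_shape, rate = prior$tau_rate,
                  log = TRUE) - log(s2)

  total_iter <- warmup + keep
  for (it in seq_len(total_iter)) {
    # --- top-level parameters, one adaptive Metropolis step per block ---
    for (b in binfo) {
      ab <- ad[[b$name]]
      pb <- length(b$idx)
      zp <- z
      zp[b$idx] <- z[b$idx] + exp(ab$ls) *
        as.vector(ab$L %*% stats::rnorm(pb))
      new_ll <- block_ll(b, zp)
      dprior <- sum(stats::dnorm(zp[b$idx], 0, prior$coef_sd, log = TRUE)) -
        sum(stats::dnorm(z[b$idx], 0, prior$coef_sd, log = TRUE))
      a <- if (is.finite(new_ll))
        exp(min(0, new_ll - llb[[b$name]] + dprior)) else 0
      if (stats::runif(1) < a) {
        z <- zp
        llb[[b$name]] <- new_ll
      }
      if (it <= warmup) {
        ab$ls <- ab$ls + (a - target) / it^0.6
        ab$S1 <- ab$S1 + z[b$idx]
        ab$S2 <- ab$S2 + tcrossprod(z[b$idx])
        if (it >= 50 && it %% 25 == 0) {
          cv <- (ab$S2 - tcrossprod(ab$S1) / it) / (it - 1)
          ch <- tryCatch(chol(cv + diag(1e-8, pb)), error = function(e) NULL)
          if (!is.null(ch)) ab$L <- t(ch)
        }
        ad[[b$name]] <- ab
      }
    }

    # --- frailties (vectorised per-subject MH) ---
    pz <- unpack_z(z, layout, formula, ctx1, ctx2, dctx)
    for (k in 1:2) {
      if (!frail[k]) next
      ctx <- if (k == 1) ctx1 else ctx2
      pk <- pz[[paste0("dir", k)]]
      eta <- if (k == 1) eta1 else eta2
      step <- exp(ls_eta[k])
      etap <- eta + step * stats::rnorm(n)
      ll_old <- direction_loglik_rows(ctx, formula$family[k], pk$log_theta0,
                                      pk$alpha, pk$beta, eta)
      ll_new <- direction_loglik_rows(ctx, formula$family[k], pk$log_theta0,
                                      pk$alpha, pk$beta, etap)
      ll_new[!is.finite(ll_new)] <- -Inf
      delta <- numeric(n)
      if (ctx$n_rows) {
        rs <- rowsum(ll_new - ll_old, ctx$subj)
        delta[as.integer(rownames(rs))] <- rs[, 1]
      }
      sdk <- sqrt(max(sig[k], 1e-12))
      delta <- delta + stats::dnorm(etap, 0, sdk, log = TRUE) -
        stats::dnorm(eta, 0, sdk, log = TRUE)
      acc <- stats::runif(n) < exp(pmin(0, delta))
      eta[acc] <- etap[acc]
      if (it <= warmup)
        ls_eta[k] <- ls_eta[k] + (mean(pmin(1, exp(delta))) - 0.44) / it^0.6
      # --- sigma^2 Gibbs ---
      tau <- stats::rgamma(1, prior$tau_shape + n / 2,
                           prior$tau_rate + sum(eta^2) / 2)
      sig[k] <- 1 / tau
      # --- joint rescale of (eta, sigma2): traverses the funnel that the
      # centred Gibbs scheme mixes slowly through when sigma2 is small.
      # eta' = eta * e^(eps/2), sigma2' = sigma2 * e^(eps); the frailty
      # prior term cancels the Jacobian exactly, leaving the likelihood
      # ratio times the (log-scale) prior ratio of sigma2.
      ll_cur <- direction_loglik_rows(ctx, formula$family[k], pk$log_theta0,
                                      pk$alpha, pk$beta, eta)
      eps <- stats::rnorm(1, 0, 0.6)
      s2p <- sig[k] * exp(eps)
      etap <- eta * exp(eps / 2)
      ll_res <- direction_loglik_rows(ctx, formula$family[k], pk$log_theta0,
                                      pk$alpha, pk$beta, etap)
      ll_res[!is.finite(ll_res)] <- -Inf
      dlt <- sum(ll_res) - sum(ll_cur) + lps2(s2p) - lps2(sig[k])
      if (is.finite(dlt) && stats::runif(1) < exp(min(0, dlt))) {
        eta <- etap
        ll_cur <- ll_res
        sig[k] <- s2p
      }
      llb[[paste0("dir", k)]] <- sum(ll_cur)
      if (k == 1) eta1 <- eta else eta2 <- eta
      if (it > warmup) {
        if (k == 1) eta1_acc <- eta1_acc + eta1
        else eta2_acc <- eta2_acc + eta2
      }
    }

    # --- record ---
    if (it > warmup) {
      j <- it - warmup
      zmat[j, ] <- z
      nat[j, ] <- report_natural(z, sig, frail, formula, layout,
                                 ctx1, ctx2, dctx)
      dev[j] <- -2 * sum(llb)
    }
  }

  colnames(nat) <- natural_names(formula, layout, frail)
  list(nat = nat, z = zmat, deviance = dev,
       eta1_mean = if (frail[1]) eta1_acc / keep else numeric(n),
       eta2_mean = if (frail[2]) eta2_acc / keep else numeric(n))
}

# map unconstrained z (centred parameterisation) to reported natural-scale
# parameters; theta0 is transformed back to the uncentred link
report_natural <- function(z, sig, frail, formula, layout, ctx1, ctx2, dctx) {
  pz <- unpack_z(z, layout, formula, ctx1, ctx2, dctx)
  out <- numeric(0)
  for (k in 1:2) {
    ctx <- if (k == 1) ctx1 else ctx2
    pk <- pz[[paste0("dir", k)]]
    lt0 <- pk$log_theta0
    cn <- colnames(ctx$X)
    if (ctx$sl_center != 0 && "log_study_length" %in% cn)
      lt0 <- lt0 - pk$beta[match("log_study_length", cn)] * ctx$sl_center
    out <- c(out, exp(lt0), pk$alpha, pk$beta,
             if (frail[k]) sig[k])
  }
  if (!is.null(dctx)) {
    pd <- pz$dropout
    lt0 <- pd$log_theta0
    cn <- colnames(dctx$X)
    if (dctx$sl_center != 0 && "log_study_length" %in% cn)
      lt0 <- lt0 - pd$beta[match("log_study_length", cn)] * dctx$sl_center
    out <- c(out, exp(lt0), pd$alpha, pd$beta)
  }
  out
}

natural_names <- function(formula, layout, frail) {
  nm <- character(0)
  for (k in 1:2) {
    dir_names <- layout$names[layout$block == paste0("dir", k)]
    nm <- c(nm, dir_names, if (frail[k]) sprintf("sigma2_%d", k))
  }
  c(nm, layout$names[layout$block == "dropout"])
}

#' @export
print.copd_fit <- function(x, ...) {
  cat("Two-state semi-Markov model fit (",
      paste(unique(x$formula$family), collapse = "/"), ")\n", sep = "")
  cat("  chains:", x$control$chains, " draws/chain:", x$control$draws,
      " DIC:", round(x$dic, 1), " pD:", round(x$pd, 1), "\n")
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' @export
summary.copd_fit <- function(object, ...) object$summary

#' Deviance information criterion of a fit
#'
#' Returns \eqn{DIC = \bar D + p_D} with \eqn{p_D = \bar D - D(\hat\theta)},
#' both computed at fit time from the per-draw deviance trace and the plug-in
#' deviance at the posterior mean of the unconstrained parameters. Lower DIC
#' indicates better fit after the complexity penalty; differences below 2
#' should be read as ties.
#'
#' @param fit A \code{copd_fit}.
#' @return Named vector \code{c(DIC =, pD =)}.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "copd_fit") || inherits(fit, "dropout_fit"))
  c(DIC = fit$dic, pD = fit$pd)
}

# split-Rhat and a simple initial-positive-sequence effective sample size
summarize_draws <- function(draws, par_cols, n_chains) {
  out <- lapply(par_cols, function(pc) {
    v <- draws[[pc]]
    qs <- stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
    per_chain <- split(v, draws$chain)
    halves <- unlist(lapply(per_chain, function(x) {
      h <- length(x) %/% 2
      list(x[seq_len(h)], x[(h + 1):(2 * h)])
    }), recursive = FALSE)
    data.frame(parameter = pc, median = qs[1], q2.5 = qs[2], q97.5 = qs[3],
               rhat = rhat_split(halves), ess = ess_basic(per_chain))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

rhat_split <- function(halves) {
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(per_chain) {
  total <- sum(lengths(per_chain))
  rho_sum <- mean(vapply(per_chain, function(x) {
    if (length(x) < 10 || stats::var(x) == 0) return(0)
    ac <- stats::acf(x, lag.max = min(100, length(x) - 1), plot = FALSE,
                     demean = TRUE)$acf[-1]
    neg <- which(ac < 0)
    if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
    sum(ac)
  }, 0))
  max(1, total / (1 + 2 * rho_sum))
}
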