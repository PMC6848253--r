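#' Posterior predictive check
#'
#' For each replicate, a parameter vector is drawn from the posterior, a full
#' trial with the observed design (same subjects, covariates and study
#' lengths) is simulated, and summary statistics are compared with the
#' observed data: total number of observations (sojourn records), number of
#' observations in each state, total and mean number of exacerbations per
#' subject, and the dropout count. The tail probability is the two-sided
#' probability of a replicate at least as extreme as the observed value.
#'
#' When the fitted dropout submodel uses event-derived covariates (number of
#' exacerbations, time in state 2) dropout cannot be simulated generatively
#' and is omitted from the replicates.
#'
#' @param fit A [fit_two_state()] result.
#' @param dataset The observed [trial_dataset()].
#' @param n_replicates Number of simulated datasets (default 100).
#' @param seed Seed controlling both the posterior draw selection and the
#'   replicate simulations (replicate \code{r} uses \code{seed + r}).
#' @return A \code{ppc_report}: data frame with one row per statistic
#'   (\code{observed}, simulated mean and 2.5/97.5 percentiles,
#'   \code{tail_prob}) with the replicate statistics in
#'   \code{attr(, "replicates")}.
#' @export
ppc <- function(fit, dataset, n_replicates = 100, seed) {
  stopifnot(inherits(fit, "copd_fit"), inherits(dataset, "trial_dataset"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  sims <- replicate_trials(fit, dataset, n_replicates, seed)
  obs <- ppc_statistics(dataset)
  stat_mat <- vapply(sims, ppc_statistics, obs)
  out <- data.frame(statistic = names(obs), observed = as.numeric(obs),
                    sim_mean = apply(stat_mat, 1, mean),
                    sim_lo = apply(stat_mat, 1, stats::quantile, 0.025),
                    sim_hi = apply(stat_mat, 1, stats::quantile, 0.975),
                    row.names = NULL)
  out$tail_prob <- vapply(seq_along(obs), function(i) {
    lo <- mean(stat_mat[i, ] <= obs[i])
    hi <- mean(stat_mat[i, ] >= obs[i])
    min(1, 2 * min(lo, hi))
  }, 0)
  structure(out, class = c("ppc_report", "data.frame"),
            replicates = stat_mat)
}

ppc_statistics <- function(dataset) {
  soj <- dataset$sojourns
  c(n_obs_total = nrow(soj),
    n_obs_state1 = sum(soj$state == 1),
    n_obs_state2 = sum(soj$state == 2),
    mean_exacerbations = sum(soj$state == 2) / nrow(dataset$subjects),
    n_dropouts = sum(dataset$subjects$dropout_flag))
}

# simulate n_replicates design-matched trials from posterior draws
replicate_trials <- function(fit, dataset, n_replicates, seed) {
  set.seed(seed)
  idx <- sample.int(nrow(fit$draws), n_replicates, replace = TRUE)
  lapply(seq_len(n_replicates), function(r) {
    sp <- draw_to_specs(fit, idx[r])
    simulate_with_subjects(dataset$subjects, sp$spec1, sp$spec2,
                           dropout = sp$dropout,
                           dropout_window = dataset$dropout_window,
                           seed = seed + r)
  })
}

# map one posterior draw (row of fit$draws) to simulation specs on the
# uncentred link parameterisation
draw_to_specs <- function(fit, row) {
  d <- fit$draws[row, , drop = FALSE]
  f <- fit$formula
  get_beta <- function(prefix, covs, sl) {
    nm <- c(if (sl) "log_study_length", covs)
    if (!length(nm)) return(numeric(0))
    b <- vapply(nm, function(cv) d[[paste0(prefix, cv)]], 0)
    names(b) <- nm
    b
  }
  specs <- lapply(1:2, function(k) {
    fam <- f$family[k]
    transition_spec(fam, theta0 = d[[sprintf("theta0_%d", k)]],
                    alpha = if (fam != "exponential")
                      d[[sprintf("alpha_%d", k)]],
                    beta = get_beta(sprintf("beta_%d_", k),
                                    f$covariates[[k]], fit$sl_term),
                    sigma2 = if (f$frailty[k]) d[[sprintf("sigma2_%d", k)]]
                             else 0)
  })
  dropout <- NULL
  if (!is.null(f$dropout)) {
    dcov <- f$dropout$covariates
    if (!any(dcov %in% c("n_exacerbations", "state2_time"))) {
      fam <- f$dropout$family
      dropout <- list(family = fam, theta0 = d[["dropout_theta0"]],
                      alpha = if (fam != "exponential") d[["dropout_alpha"]],
                      beta = get_beta("dropout_beta_", dcov, fit$sl_term))
    }
  }
  list(spec1 = specs[[1]], spec2 = specs[[2]], dropout = dropout)
}

#' Choose visual-predictive-check bins by one-dimensional k-means
#'
#' Runs k-means on the raw observed durations for k = 1..k_max and picks the
#' number of bins at the elbow of the within-cluster sum of squares (the
#' largest second difference). Bin boundaries are the midpoints between
#' adjacent cluster centres, so the bins partition the duration range and
#' every observed duration falls in exactly one bin.
#'
#' @param durations Observed durations (days).
#' @param k_max Largest number of clusters tried (default 8).
#' @param k Optional manual override of the elbow choice.
#' @param seed Seed for the k-means restarts (10 restarts per k).
#' @return A \code{vpc_binning}: list with \code{k}, \code{boundaries}
#'   (length k + 1, outer edges at -Inf/Inf), \code{centers}, \code{wss}.
#' @export
choose_bins <- function(durations, k_max = 8, k = NULL, seed = 1) {
  durations <- durations[is.finite(durations)]
  n_distinct <- length(unique(durations))
  if (n_distinct < 2) {
    return(structure(list(k = 1L, boundaries = c(-Inf, Inf),
                          centers = mean(durations),
                          wss = 0), class = "vpc_binning"))
  }
  if (k_max > n_distinct) {
    warning("k_max larger than the number of distinct durations; capped",
            call. = FALSE)
    k_max <- n_distinct
  }
  set.seed(seed)
  km_wss <- function(kk) {
    if (kk == 1) return(sum((durations - mean(durations))^2))
    if (kk == n_distinct) return(  # one centre per distinct value
      sum((durations - ave(durations, durations))^2))
    stats::kmeans(durations, centers = kk, nstart = 10,
                  iter.max = 50)$tot.withinss
  }
  wss <- vapply(seq_len(k_max), km_wss, 0)
  if (is.null(k)) {
    k <- if (k_max < 3) k_max
         else {
           d2 <- wss[1:(k_max - 2)] - 2 * wss[2:(k_max - 1)] + wss[3:k_max]
           which.max(d2) + 1L
         }
  }
  set.seed(seed)
  km <- if (k == 1) list(centers = matrix(mean(durations)))
        else if (k == n_distinct)
          list(centers = matrix(sort(unique(durations))))
        else stats::kmeans(durations, centers = k, nstart = 10,
                           iter.max = 50)
  centers <- sort(as.vector(km$centers))
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  structure(list(k = as.integer(k), boundaries = c(-Inf, mids, Inf),
                 centers = centers, wss = wss),
            class = "vpc_binning")
}

#' @export
print.vpc_binning <- function(x, ...) {
  cat("VPC binning: k =", x$k, "bins; interior boundaries at",
      paste(signif(x$boundaries[is.finite(x$boundaries)], 4),
            collapse = ", "), "\n")
  invisible(x)
}

#' Visual predictive check
#'
#' Bins the observed completed sojourn durations per state (k-means elbow
#' binning unless a binning is supplied), simulates design-matched replicate
#' trials from the posterior, and reports per-bin observed counts against
#' the 2.5/97.5 percentiles of the replicate counts. Also returns the
#' per-subject exacerbation-count VPC (number of subjects with 0, 1, 2, ...
#' exacerbations).
#'
#' @inheritParams ppc
#' @param binning Optional list with elements \code{state1}, \code{state2}
#'   of [choose_bins()] results built from the observed durations.
#' @param k_max Passed to [choose_bins()].
#' @return A \code{vpc_report}: list of data frames \code{state1},
#'   \code{state2} (bin, observed, lo, hi, covered) and \code{counts}
#'   (exacerbations per subject).
#' @export
vpc <- function(fit, dataset, n_replicates = 100, seed, binning = NULL,
                k_max = 8) {
  stopifnot(inherits(fit, "copd_fit"), inherits(dataset, "trial_dataset"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  obs_dur <- function(ds, st)
    ds$sojourns$duration[ds$sojourns$state == st & ds$sojourns$event]
  if (is.null(binning))
    binning <- list(state1 = choose_bins(obs_dur(dataset, 1), k_max),
                    state2 = choose_bins(obs_dur(dataset, 2), k_max))
  sims <- replicate_trials(fit, dataset, n_replicates, seed)

  bin_counts <- function(x, b) {
    as.vector(table(cut(x, b$boundaries, include.lowest = TRUE)))
  }
  state_tab <- function(st) {
    b <- binning[[paste0("state", st)]]
    obs <- bin_counts(obs_dur(dataset, st), b)
    sim <- vapply(sims, function(s) bin_counts(obs_dur(s, st), b),
                  numeric(b$k))
    sim <- matrix(sim, nrow = b$k)
    lo <- apply(sim, 1, stats::quantile, 0.025)
    hi <- apply(sim, 1, stats::quantile, 0.975)
    data.frame(bin = seq_len(b$k), observed = obs, lo = lo, hi = hi,
               covered = obs >= lo & obs <= hi)
  }

  exac_counts <- function(ds) {
    cnt <- tapply(ds$sojourns$state == 2, ds$sojourns$subject_id, sum)
    cnt <- cnt[ds$subjects$subject_id]
    cnt[is.na(cnt)] <- 0
    cnt
  }
  obs_cnt <- exac_counts(dataset)
  kmax_cnt <- max(obs_cnt, vapply(sims, function(s) max(exac_counts(s)), 0))
  cnt_tab <- function(x) tabulate(x + 1, nbins = kmax_cnt + 1)
  sim_cnt <- vapply(sims, function(s) cnt_tab(exac_counts(s)),
                    numeric(kmax_cnt + 1))
  sim_cnt <- matrix(sim_cnt, nrow = kmax_cnt + 1)
  counts <- data.frame(
    exacerbations = 0:kmax_cnt, observed = cnt_tab(obs_cnt),
    lo = apply(sim_cnt, 1, stats::quantile, 0.025),
    hi = apply(sim_cnt, 1, stats::quantile, 0.975))
  counts$covered <- counts$observed >= counts$lo & counts$observed <= counts$hi

  structure(list(state1 = state_tab(1), state2 = state_tab(2),
                 counts = counts, binning = binning),
            class = "vpc_report")
}

#' @export
print.vpc_report <- function(x, ...) {
  for (st in c("state1", "state2")) {
    tab <- x[[st]]
    cat(st, ": ", sum(tab$covered), "/", nrow(tab),
        " bins covered by the simulated 95% interval\n", sep = "")
  }
  cat("exacerbation counts: ", sum(x$counts$covered), "/", nrow(x$counts),
      " covered\n", sep = "")
  invisible(x)
}

#' @export
plot.vpc_report <- function(x, which = c("state1", "state2", "counts"), ...) {
  which <- match.arg(which)
  tab <- x[[which]]
  xx <- seq_len(nrow(tab))
  ylim <- c(0, max(tab$observed, tab$hi) * 1.05)
  graphics::barplot(tab$observed, names.arg = xx, ylim = ylim,
                    xlab = if (which == "counts") "exacerbations per subject"
                           else "duration bin",
                    ylab = "count", main = which, ...)
  at <- seq_along(xx) * 1.2 - 0.5
  graphics::arrows(at, tab$lo, at, tab$hi, angle = 90, code = 3,
                   length = 0.04, col = "red3")
  invisible(x)
}
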