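#' Truncate follow-up of a trial dataset
#'
#' Cuts every subject's observation at day \code{L}: sojourns ending after
#' \code{L} are re-censored at \code{L} with their duration recomputed,
#' later sojourns are dropped, study lengths become \code{L} and the dropout
#' flag is recomputed under the window rule against the new study end.
#' A transition falling within half a day of \code{L} is recorded as
#' censoring at \code{L} (the package's day-resolution convention), and
#' truncation at the full study length leaves the dataset unchanged.
#'
#' @param dataset A [trial_dataset()].
#' @param L New follow-up limit in days.
#' @return A [trial_dataset()] with all observation limited to \code{[0, L]}.
#' @export
truncate_followup <- function(dataset, L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (L <= 0 || L > max(dataset$subjects$study_length))
    stop("`L` must be in (0, max study length]", call. = FALSE)
  sub <- dataset$subjects
  soj <- dataset$sojourns
  pieces <- lapply(split(soj, soj$subject_id), function(d) {
    d <- d[order(d$episode), ]
    start <- cumsum(c(0, d$duration[-nrow(d)]))
    end <- start + d$duration
    keep <- start < L - .min_sojourn
    d <- d[keep, , drop = FALSE]
    if (!nrow(d)) return(d)
    last <- nrow(d)
    if (end[last] > L - .min_sojourn) {
      d$duration[last] <- L - start[last]
      d$event[last] <- FALSE
    }
    d
  })
  soj <- do.call(rbind, pieces)
  rownames(soj) <- NULL
  sub$study_length <- pmin(sub$study_length, L)
  sub$dropout_time[!is.na(sub$dropout_time) & sub$dropout_time >= L] <-
    NA_real_
  fu <- tapply(soj$duration, soj$subject_id, sum)[sub$subject_id]
  sub$dropout_flag <-
    as.vector(fu < sub$study_length - dataset$dropout_window - 1e-9)
  trial_dataset(sub, soj, dropout_window = dataset$dropout_window)
}

#' Subsample subjects without replacement
#'
#' Randomly selects \code{n_per_arm} subjects from each treatment arm
#' (sampling without replacement), keeping their full histories, to explore
#' how shrinking the sample affects drug-effect identification.
#'
#' @param dataset A [trial_dataset()].
#' @param n_per_arm Subjects to keep per arm.
#' @param seed Seed for the random selection.
#' @return A smaller [trial_dataset()].
#' @export
subsample_subjects <- function(dataset, n_per_arm, seed) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  sub <- dataset$subjects
  keep <- unlist(lapply(split(sub$subject_id, sub$treatment), function(ids) {
    if (n_per_arm > length(ids))
      stop("`n_per_arm` exceeds the available arm size (",
           length(ids), ")", call. = FALSE)
    sample(ids, n_per_arm)
  }), use.names = FALSE)
  sub <- sub[sub$subject_id %in% keep, , drop = FALSE]
  soj <- dataset$sojourns[dataset$sojourns$subject_id %in% keep, ,
                          drop = FALSE]
  rownames(sub) <- rownames(soj) <- NULL
  trial_dataset(sub, soj, dropout_window = dataset$dropout_window)
}

#' Design experiment: refit under a modified design
#'
#' Applies a design modification — subsampling \code{n} subjects per arm or
#' truncating follow-up at \code{L} days — refits the model, and summarises
#' the drug effect as a transition-rate-ratio curve together with a
#' significance verdict (whether the 95% band excludes 1 anywhere on the
#' grid).
#'
#' @param dataset A [trial_dataset()].
#' @param modification A list: \code{list(type = "subsample", n = 100)} or
#'   \code{list(type = "truncate", L = 120)}.
#' @param formula,control Passed to [fit_two_state()].
#' @param direction,reference,alternative,times Passed to [rate_ratio()].
#' @param seed Seed for the subsampling draw (defaults to the sampler seed).
#' @return A list with \code{dataset} (modified), \code{fit}, \code{curve}
#'   and \code{significant} (logical verdict).
#' @export
design_experiment <- function(dataset, modification, formula, control,
                              direction = 1,
                              reference = list(treatment = 0),
                              alternative = list(treatment = 1),
                              times = NULL, seed = control$seed) {
  mod <- switch(modification$type,
    subsample = subsample_subjects(dataset, modification$n, seed = seed),
    truncate = truncate_followup(dataset, modification$L),
    stop("unknown modification type '", modification$type, "'",
         call. = FALSE))
  fit <- fit_two_state(mod, formula, control)
  curve <- rate_ratio(fit, direction, reference, alternative, times)
  list(dataset = mod, fit = fit, curve = curve,
       significant = any(curve$lo > 1 | curve$hi < 1))
}

#' Extrapolate a short-study fit to a longer horizon
#'
#' Simulates replicate trials out to \code{horizon} days from the posterior
#' of a fit obtained on truncated (short) data, and compares the
#' exacerbation-count distribution against the observed full-length data
#' restricted to the same horizon. Interval widths grow with the horizon,
#' quantifying how far short-study estimates can be trusted.
#'
#' @param fit A [fit_two_state()] result (typically fitted on truncated
#'   data).
#' @param horizon Prediction horizon in days (at least the fitted follow-up).
#' @param full_dataset The observed full-length [trial_dataset()].
#' @param n_replicates,seed As in [ppc()].
#' @return A data frame (exacerbations, observed subjects, lo, hi, covered)
#'   with the mean interval width in \code{attr(, "interval_width")}.
#' @export
extrapolate <- function(fit, horizon, full_dataset, n_replicates = 100,
                        seed) {
  stopifnot(inherits(fit, "copd_fit"),
            inherits(full_dataset, "trial_dataset"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (horizon < max(fit$subjects$study_length))
    stop("`horizon` must be at least the fitted follow-up length",
         call. = FALSE)

  # observed exacerbation onsets within the horizon
  obs_cnt <- vapply(split(full_dataset$sojourns,
                          full_dataset$sojourns$subject_id), function(d) {
    d <- d[order(d$episode), ]
    start <- cumsum(c(0, d$duration[-nrow(d)]))
    sum(d$state == 2 & start < horizon)
  }, 0)

  subjects <- fit$subjects
  subjects$study_length <- horizon
  set.seed(seed)
  idx <- sample.int(nrow(fit$draws), n_replicates, replace = TRUE)
  sims <- lapply(seq_len(n_replicates), function(r) {
    sp <- draw_to_specs(fit, idx[r])
    simulate_with_subjects(subjects, sp$spec1, sp$spec2,
                           dropout = sp$dropout,
                           dropout_window = fit$dropout_window,
                           seed = seed + r)
  })
  sim_cnt_one <- function(ds) {
    cnt <- tapply(ds$sojourns$state == 2, ds$sojourns$subject_id, sum)
    cnt <- cnt[ds$subjects$subject_id]
    cnt[is.na(cnt)] <- 0
    cnt
  }
  kmax <- max(obs_cnt, vapply(sims, function(s) max(sim_cnt_one(s)), 0))
  tab <- function(x) tabulate(x + 1, nbins = kmax + 1)
  sim_tab <- vapply(sims, function(s) tab(sim_cnt_one(s)),
                    numeric(kmax + 1))
  sim_tab <- matrix(sim_tab, nrow = kmax + 1)
  out <- data.frame(exacerbations = 0:kmax, observed = tab(obs_cnt),
                    lo = apply(sim_tab, 1, stats::quantile, 0.025),
                    hi = apply(sim_tab, 1, stats::quantile, 0.975))
  out$covered <- out$observed >= out$lo & out$observed <= out$hi
  # predictive uncertainty of the mean exacerbation count per subject
  sim_means <- vapply(sims, function(s) mean(sim_cnt_one(s)), 0)
  width <- diff(stats::quantile(sim_means, c(0.025, 0.975), names = FALSE))
  structure(out, class = c("extrapolation_vpc", "data.frame"),
            horizon = horizon, interval_width = width)
}
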