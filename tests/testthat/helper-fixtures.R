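# shared fixtures and small helpers for the suite

quick_control <- function(seed = 1, chains = 2, draws = 300, warmup = 300)
  sampler_control(chains = chains, draws = draws, warmup = warmup,
                  seed = seed)

# a tiny hand-built two-subject dataset used by data-model tests
tiny_trial <- function(dropout_window = 30) {
  subjects <- data.frame(
    subject_id = c("a", "b"),
    treatment = c(0, 1), disease_stage = c(1, 0), smoke = c(0, 1),
    pack_years = c(40, 25.5), season = c(0, 0),
    study_length = c(364, 364),
    dropout_time = c(NA, 200), dropout_flag = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  sojourns <- rbind(
    episodes_to_sojourns(data.frame(onset = c(100, 250),
                                    resolution = c(110, 260)), 364, "a"),
    episodes_to_sojourns(data.frame(onset = 150, resolution = 160), 200, "b"))
  trial_dataset(subjects, sojourns, dropout_window = dropout_window)
}

# memoised small log-logistic fits reused across diagnostic/effect tests
shared_fit_env <- new.env()
shared_small_fit <- function(trial_seed = 77) {
  key <- paste0("f", trial_seed)
  if (is.null(shared_fit_env[[key]])) {
    trial <- simulate_trial(copd_trial_config(
      n_per_arm = 60, seed = trial_seed, treatment_beta1 = 0.5, sigma2 = 0))
    formula <- two_state_formula("loglogistic", covariates1 = "treatment",
                                 frailty1 = FALSE, frailty2 = FALSE)
    fit <- suppressWarnings(
      fit_two_state(trial, formula,
                    quick_control(seed = 5, draws = 500, warmup = 500)))
    shared_fit_env[[key]] <- list(fit = fit, trial = trial)
  }
  shared_fit_env[[key]]
}

# exact 1-d k-means by dynamic programming: the brute-force oracle for the
# elbow rule (independent of stats::kmeans)
optimal_wss_1d <- function(x, k_max) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) {   # within-SS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k_max, n)
  for (j in 1:n) D[1, j] <- ssq(1, j)
  if (k_max > 1) {
    for (k in 2:k_max) {
      for (j in k:n) {
        D[k, j] <- min(vapply(k:j, function(i)
          D[k - 1, i - 1] + ssq(i, j), 0))
      }
    }
  }
  D[, n]
}
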