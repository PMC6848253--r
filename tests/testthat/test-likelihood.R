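test_that("sojourn contributions are log f when observed, log S when censored", {
  expect_equal(sojourn_loglik(2, TRUE, "exponential", theta = 0.5),
               log(0.5) - 1, tolerance = 1e-12)
  expect_equal(sojourn_loglik(2, FALSE, "exponential", theta = 0.5), -1,
               tolerance = 1e-12)
  # f = h * S identity across families at assorted parameter values
  cases <- list(list("weibull", 0.005, 1.3), list("gompertz", 0.015, -0.002),
                list("loglogistic", 70, 1.34), list("exponential", 0.02, NULL))
  for (cs in cases) {
    t <- c(0.6, 4, 33, 190)
    expect_equal(sojourn_loglik(t, TRUE, cs[[1]], cs[[2]], cs[[3]]),
                 log(sojourn_density(cs[[1]], t, cs[[2]], cs[[3]])),
                 tolerance = 1e-10, info = cs[[1]])
  }
  expect_error(sojourn_loglik(-1, TRUE, "exponential", 0.5), "duration")
})

make_params <- function(formula, trial, theta0 = c(100, 9),
                        alpha = c(1.3, 2.5), beta1 = numeric(0)) {
  n <- n_subjects(trial)
  list(dir1 = list(theta0 = theta0[1], alpha = alpha[1], beta = beta1,
                   sigma2 = 0.1, eta = rep(0, n)),
       dir2 = list(theta0 = theta0[2], alpha = alpha[2], beta = numeric(0),
                   sigma2 = 0.1, eta = rep(0, n)))
}

test_that("total log-likelihood is additive and matches a brute-force loop", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 8, seed = 31,
                                            two_arms = FALSE))
  formula <- two_state_formula("loglogistic", frailty1 = FALSE,
                               frailty2 = FALSE)
  params <- make_params(formula, trial)
  got <- total_loglik(trial, formula, params)

  # independent per-row recomputation through the public kernels
  want <- 0
  for (i in seq_len(nrow(trial$sojourns))) {
    row <- trial$sojourns[i, ]
    th <- if (row$state == 1) 100 else 9
    al <- if (row$state == 1) 1.3 else 2.5
    S <- survival("loglogistic", row$duration, th, al)
    want <- want + if (row$event)
      log(hazard("loglogistic", row$duration, th, al) * S) else log(S)
  }
  expect_equal(got, want, tolerance = 1e-10)

  # doubling the dataset doubles the total at fixed parameters
  sub2 <- trial$subjects
  sub2$subject_id <- paste0("dup_", sub2$subject_id)
  soj2 <- trial$sojourns
  soj2$subject_id <- paste0("dup_", soj2$subject_id)
  doubled <- trial_dataset(rbind(trial$subjects, sub2),
                           rbind(trial$sojourns, soj2))
  params2 <- make_params(formula, doubled)
  expect_equal(total_loglik(doubled, formula, params2), 2 * got,
               tolerance = 1e-10)
})

test_that("a singleton censored record contributes exactly log S", {
  sub <- tiny_trial()$subjects[1, ]
  soj <- data.frame(subject_id = "a", episode = 1, state = 1,
                    duration = 364, event = FALSE)
  trial <- trial_dataset(sub, soj)
  formula <- two_state_formula("weibull", frailty1 = FALSE, frailty2 = FALSE)
  params <- list(dir1 = list(theta0 = 0.004, alpha = 1.2),
                 dir2 = list(theta0 = 0.01, alpha = 1.5))
  expect_equal(total_loglik(trial, formula, params),
               sojourn_loglik(364, FALSE, "weibull", 0.004, 1.2),
               tolerance = 1e-12)
})

test_that("frailty terms add the normal log-prior of eta", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 5, seed = 32,
                                            two_arms = FALSE))
  n <- n_subjects(trial)
  formula_off <- two_state_formula("loglogistic", frailty1 = FALSE,
                                   frailty2 = FALSE)
  formula_on <- two_state_formula("loglogistic", frailty1 = TRUE,
                                  frailty2 = FALSE)
  set.seed(1)
  eta <- stats::rnorm(n, 0, 0.3)
  p_off <- make_params(formula_off, trial)
  p_on <- p_off
  p_on$dir1$eta <- eta

  base <- total_loglik(trial, formula_off, p_off)
  got <- total_loglik(trial, formula_on, p_on)
  # difference = data-likelihood shift from eta + the eta prior
  manual <- 0
  for (j in seq_len(n)) {
    id <- trial$subjects$subject_id[j]
    rows <- trial$sojourns[trial$sojourns$subject_id == id &
                             trial$sojourns$state == 1, ]
    manual <- manual +
      sum(sojourn_loglik(rows$duration, rows$event, "loglogistic",
                         100 * exp(eta[j]), 1.3)) -
      sum(sojourn_loglik(rows$duration, rows$event, "loglogistic", 100, 1.3))
  }
  prior <- sum(stats::dnorm(eta, 0, sqrt(0.1), log = TRUE))
  expect_equal(got - base, manual + prior, tolerance = 1e-10)
})

test_that("out-of-domain parameters yield -Inf, not an exception", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 5, seed = 33,
                                            two_arms = FALSE))
  formula <- two_state_formula("loglogistic", frailty1 = FALSE,
                               frailty2 = FALSE)
  p <- make_params(formula, trial)
  p$dir1$theta0 <- -1
  expect_identical(total_loglik(trial, formula, p), -Inf)
  p <- make_params(formula, trial)
  p$dir2$alpha <- -0.5
  expect_identical(total_loglik(trial, formula, p), -Inf)
})
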