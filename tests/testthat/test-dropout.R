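test_that("with no dropouts the likelihood is the sum of log survivals", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 25, seed = 51,
                                            two_arms = FALSE))
  expect_false(any(trial$subjects$dropout_flag))
  df <- dropout_formula("weibull")
  dctx <- copdsemi:::dropout_context(trial, df, sl_term = FALSE)
  ll <- sum(copdsemi:::direction_loglik_rows(
    dctx, "weibull", log(0.001), 1.2, numeric(0), rep(0, 25)))
  want <- sum(log(survival("weibull", trial$subjects$study_length,
                           0.001, 1.2)))
  expect_equal(ll, want, tolerance = 1e-10)
  expect_warning(
    fit_dropout(trial, df, quick_control(seed = 1, draws = 100,
                                         warmup = 100)),
    "unidentifiable")
})

test_that("joint deviance is the sum of the two factors (MAR additivity)", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 40, seed = 52,
                                            two_arms = FALSE,
                                            dropout = TRUE))
  base <- two_state_formula("loglogistic", frailty1 = FALSE,
                            frailty2 = FALSE)
  joint <- attach_dropout(base, dropout_formula("loglogistic",
                                                "disease_stage"))
  params <- list(
    dir1 = list(theta0 = 150, alpha = 1.34),
    dir2 = list(theta0 = 10, alpha = 2.97),
    dropout = list(theta0 = 3500, alpha = 1.5,
                   beta = c(disease_stage = -0.68)))
  ll_two_state <- total_loglik(trial, base, params[1:2])
  ll_joint <- total_loglik(trial, joint, params)
  # recompute the dropout factor independently: f at the dropout time for
  # dropouts, S at the observed end of follow-up otherwise
  sub <- trial$subjects
  fu <- tapply(trial$sojourns$duration, trial$sojourns$subject_id,
               sum)[sub$subject_id]
  th <- 3500 * exp(-0.68 * sub$disease_stage)
  ll_drop <- sum(ifelse(sub$dropout_flag,
                        log(sojourn_density("loglogistic", fu, th, 1.5)),
                        log(survival("loglogistic", fu, th, 1.5))))
  expect_equal(ll_joint, ll_two_state + ll_drop, tolerance = 1e-10)
})

test_that("attaching dropout with null effects leaves the two-state block", {
  # a joint fit whose dropout block has matching parameters adds the same
  # dropout term to every deviance evaluation, so the two-state parameters'
  # likelihood surface (and separate-fit posterior) is unchanged under MAR
  trial <- simulate_trial(copd_trial_config(n_per_arm = 150, seed = 53,
                                            two_arms = FALSE, sigma2 = 0,
                                            family = "exponential",
                                            theta1 = 0.02, theta2 = 0.1,
                                            dropout = TRUE))
  base <- two_state_formula("exponential", frailty1 = FALSE,
                            frailty2 = FALSE)
  joint <- attach_dropout(base, dropout_formula("exponential"))
  sep <- fit_two_state(trial, base, quick_control(seed = 5, draws = 500,
                                                  warmup = 400))
  jnt <- fit_two_state(trial, joint, quick_control(seed = 5, draws = 500,
                                                   warmup = 400))
  for (p in c("theta0_1", "theta0_2")) {
    m_sep <- median(sep$draws[[p]])
    m_jnt <- median(jnt$draws[[p]])
    expect_lt(abs(log(m_jnt / m_sep)), 0.05)
  }
})

test_that("unknown dropout covariates and families are rejected", {
  expect_error(dropout_formula("gompertz"), "exponential")
  expect_error(dropout_formula("loglogistic", "eosinophils"), "covariate")
  expect_error(attach_dropout(two_state_formula(), list()), "dropout_formula")
})

test_that("dropout recovery under the sparse log-logistic scenario", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 600, seed = 54,
                                            two_arms = FALSE,
                                            dropout = TRUE))
  expect_gt(sum(trial$subjects$dropout_flag), 10)
  fit <- fit_dropout(trial,
                     dropout_formula("loglogistic", "disease_stage"),
                     quick_control(seed = 2, draws = 800, warmup = 800))
  sm <- summary(fit)
  b <- sm[sm$parameter == "dropout_beta_disease_stage", ]
  expect_lt(b$median, 0)        # current-stage subjects drop out sooner
  expect_lt(abs(b$median - (-0.68)), 0.6)
})
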