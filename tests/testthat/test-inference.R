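test_that("fits are reproducible given the seed", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 30, seed = 41,
                                            family = "exponential",
                                            theta1 = 0.02, theta2 = 0.1,
                                            sigma2 = 0, two_arms = FALSE))
  formula <- two_state_formula("exponential", frailty1 = FALSE,
                               frailty2 = FALSE)
  f1 <- fit_two_state(trial, formula, quick_control(seed = 3, draws = 150,
                                                    warmup = 150))
  f2 <- fit_two_state(trial, formula, quick_control(seed = 3, draws = 150,
                                                    warmup = 150))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$dic, f2$dic)
  f3 <- fit_two_state(trial, formula, quick_control(seed = 4, draws = 150,
                                                    warmup = 150))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("DIC obeys its defining identities", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 60, seed = 42,
                                            family = "exponential",
                                            theta1 = 0.02, theta2 = 0.1,
                                            sigma2 = 0, two_arms = FALSE))
  formula <- two_state_formula("exponential", frailty1 = FALSE,
                               frailty2 = FALSE)
  fit <- fit_two_state(trial, formula, quick_control(seed = 2))
  d <- dic(fit)
  expect_equal(unname(d["DIC"]), mean(fit$deviance) + fit$pd,
               tolerance = 1e-12)
  # plug-in deviance recomputed independently at the posterior means of the
  # unconstrained (log-scale) parameters
  lt1 <- mean(log(fit$draws$theta0_1))
  lt2 <- mean(log(fit$draws$theta0_2))
  d_hat <- -2 * total_loglik(trial, formula,
                             list(dir1 = list(theta0 = exp(lt1)),
                                  dir2 = list(theta0 = exp(lt2))))
  expect_equal(fit$pd, mean(fit$deviance) - d_hat, tolerance = 1e-8)
  expect_gt(fit$pd, 0)
  expect_lt(abs(fit$pd - 2), 1.5)  # two free parameters
})

test_that("exponential parameters are recovered within 10% with coverage", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 200, seed = 7,
                                            family = "exponential",
                                            theta1 = 0.02, theta2 = 0.1,
                                            sigma2 = 0, two_arms = FALSE))
  formula <- two_state_formula("exponential", frailty1 = FALSE,
                               frailty2 = FALSE)
  fit <- fit_two_state(trial, formula, quick_control(seed = 11, draws = 500,
                                                     warmup = 400))
  sm <- summary(fit)
  th1 <- sm[sm$parameter == "theta0_1", ]
  th2 <- sm[sm$parameter == "theta0_2", ]
  expect_lt(abs(th1$median / 0.02 - 1), 0.10)
  expect_lt(abs(th2$median / 0.1 - 1), 0.10)
  expect_true(th1$q2.5 <= 0.02 && th1$q97.5 >= 0.02)
  expect_true(th2$q2.5 <= 0.1 && th2$q97.5 >= 0.1)
  expect_true(all(sm$rhat < 1.05))
})

test_that("data simulated without frailty yield a near-zero variance", {
  trial <- simulate_trial(copd_trial_config(n_per_arm = 100, seed = 8,
                                            sigma2 = 0, two_arms = FALSE))
  fit <- suppressWarnings(
    fit_two_state(trial, two_state_formula("loglogistic"),
                  quick_control(seed = 12, draws = 400, warmup = 400)))
  sm <- summary(fit)
  expect_lt(sm$median[sm$parameter == "sigma2_1"], 0.05)
  expect_lt(sm$median[sm$parameter == "sigma2_2"], 0.05)
})

test_that("with no data the sampler returns the prior", {
  empty_sub <- tiny_trial()$subjects[0, ]
  empty_soj <- tiny_trial()$sojourns[0, ]
  trial <- trial_dataset(empty_sub, empty_soj)
  formula <- two_state_formula("exponential", frailty1 = FALSE,
                               frailty2 = FALSE, study_length_term = "off")
  fit <- suppressWarnings(fit_two_state(
    trial, formula,
    sampler_control(chains = 2, draws = 5000, warmup = 1500, seed = 9)))
  # theta0 draws are exp(z) with z ~ normal(0, sqrt(1000)); check z
  z <- log(fit$draws$theta0_1)
  expect_lt(abs(mean(z)), 5)
  expect_lt(abs(stats::sd(z) / sqrt(1000) - 1), 0.15)
})

test_that("draws respect parameter domains", {
  sf <- shared_small_fit()
  d <- sf$fit$draws
  expect_true(all(d$theta0_1 > 0) && all(d$theta0_2 > 0))
  expect_true(all(d$alpha_1 > 0) && all(d$alpha_2 > 0))
})
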