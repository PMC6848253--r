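# representative valid parameter sets per family (days scale)
family_cases <- list(
  list(family = "exponential", theta = 0.02, alpha = NULL),
  list(family = "weibull", theta = 0.005, alpha = 1.3),
  list(family = "gompertz", theta = 0.015, alpha = 0.004),
  list(family = "loglogistic", theta = 70, alpha = 1.34))

test_that("closed-form hazard and survival values match the printed forms", {
  expect_equal(hazard("exponential", t = c(1, 50), theta = 0.5), c(0.5, 0.5))
  # Weibull with unit shape reduces to the exponential exactly
  tt <- c(0.5, 3, 40, 200)
  expect_equal(hazard("weibull", tt, theta = 0.5, alpha = 1),
               hazard("exponential", tt, theta = 0.5), tolerance = 1e-12)
  expect_equal(survival("weibull", tt, theta = 0.5, alpha = 1),
               survival("exponential", tt, theta = 0.5), tolerance = 1e-12)
  # log-logistic at t = theta: h = alpha/(2 theta), S = 1/2
  expect_equal(hazard("loglogistic", 10, theta = 10, alpha = 2), 0.1)
  expect_equal(survival("loglogistic", 7, theta = 7, alpha = 3), 0.5)
  # Weibull survival exp(-theta t^alpha)
  expect_equal(survival("weibull", 10, theta = 0.01, alpha = 2), exp(-1),
               tolerance = 1e-8)
  # Gompertz collapses to the exponential as the shape goes to 0
  expect_equal(survival("gompertz", 2, theta = 0.5, alpha = 1e-8),
               exp(-1), tolerance = 1e-6)
  expect_equal(hazard("gompertz", 2, theta = 0.5, alpha = 1e-8), 0.5,
               tolerance = 1e-6)
  expect_equal(survival("exponential", 0, theta = 0.3), 1)
})

test_that("density equals hazard times survival and integrates to one", {
  for (cs in family_cases) {
    f <- function(t) sojourn_density(cs$family, t, cs$theta, cs$alpha)
    h <- hazard(cs$family, c(1, 10, 80), cs$theta, cs$alpha)
    S <- survival(cs$family, c(1, 10, 80), cs$theta, cs$alpha)
    expect_equal(f(c(1, 10, 80)), h * S, tolerance = 1e-12, info = cs$family)
    mass <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6, info = cs$family)
  }
})

test_that("Gompertz with negative shape leaves a never-transition mass", {
  theta <- 0.01; alpha <- -0.006
  f <- function(t) sojourn_density("gompertz", t, theta, alpha)
  mass <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
  expect_equal(mass, 1 - exp(theta / alpha), tolerance = 1e-6)
  # quantiles beyond the attainable mass are infinite
  expect_identical(sojourn_quantile("gompertz", 0.9, theta, alpha), Inf)
})

test_that("survival equals exp(minus integrated hazard) on a wide grid", {
  grid <- c(0.1, 1, 5, 20, 80, 200, 500)
  for (cs in family_cases) {
    for (t in grid) {
      cumhaz <- stats::integrate(function(u)
        hazard(cs$family, u, cs$theta, cs$alpha), 0, t,
        rel.tol = 1e-10)$value
      expect_equal(survival(cs$family, t, cs$theta, cs$alpha),
                   exp(-cumhaz), tolerance = 1e-6,
                   info = paste(cs$family, t))
    }
  }
})

test_that("kernels agree with an independent parametric-survival library", {
  t <- c(0.7, 3, 25, 130)
  expect_equal(hazard("loglogistic", t, theta = 70, alpha = 1.34),
               flexsurv::hllogis(t, shape = 1.34, scale = 70),
               tolerance = 1e-12)
  expect_equal(survival("gompertz", t, theta = 0.015, alpha = 0.004),
               1 - flexsurv::pgompertz(t, shape = 0.004, rate = 0.015),
               tolerance = 1e-12)
  # our Weibull scale is the rate-like theta in S = exp(-theta t^alpha)
  th <- 0.005; al <- 1.3
  expect_equal(survival("weibull", t, theta = th, alpha = al),
               1 - stats::pweibull(t, shape = al, scale = th^(-1 / al)),
               tolerance = 1e-12)
})

test_that("quantile inverts survival to high precision", {
  us <- c(1e-4, 0.1, 0.5, 0.9, 0.9999)
  for (cs in family_cases) {
    q <- sojourn_quantile(cs$family, us, cs$theta, cs$alpha)
    expect_equal(survival(cs$family, q, cs$theta, cs$alpha), 1 - us,
                 tolerance = 1e-8, info = cs$family)
    # round trip t -> u -> t
    tt <- c(0.5, 7, 90)
    u <- 1 - survival(cs$family, tt, cs$theta, cs$alpha)
    expect_equal(sojourn_quantile(cs$family, u, cs$theta, cs$alpha), tt,
                 tolerance = 1e-8, info = cs$family)
  }
  expect_equal(sojourn_quantile("loglogistic", 0.5, theta = 7, alpha = 3), 7)
  expect_equal(sojourn_quantile("exponential", 1 - exp(-1), theta = 0.5), 2)
})

test_that("domain errors name the offending argument", {
  expect_error(hazard("exponential", -1, theta = 0.5), "`t`")
  expect_error(hazard("weibull", 1, theta = -2, alpha = 1), "`theta`")
  expect_error(hazard("weibull", 1, theta = 1, alpha = -1), "`alpha`")
  expect_error(hazard("loglogistic", 1, theta = 1, alpha = NULL), "`alpha`")
  expect_error(sojourn_quantile("exponential", 1.2, theta = 1), "`u`")
  expect_error(sojourn_quantile("exponential", 0, theta = 1), "`u`")
  expect_error(hazard("lognormal", 1, theta = 1), "family")
})

test_that("the covariate/frailty link is positive and log-linear", {
  sp <- transition_spec("loglogistic", theta0 = 0.02, alpha = 1.3,
                        beta = c(disease_stage = -0.40), sigma2 = 0.1)
  cov0 <- list(disease_stage = 0, study_length = 364)
  cov1 <- list(disease_stage = 1, study_length = 364)
  expect_equal(link_subject_params(sp, cov0, eta = 0)$theta, 0.02)
  expect_equal(link_subject_params(sp, cov1, eta = 0)$theta,
               0.02 * exp(-0.40), tolerance = 1e-12)
  expect_equal(link_subject_params(sp, cov0, eta = 0.3)$theta,
               0.02 * exp(0.3), tolerance = 1e-12)
  # exact additivity of log theta in eta and each beta * X term
  sp2 <- transition_spec("weibull", theta0 = 0.01, alpha = 1.1,
                         beta = c(log_study_length = 0.2, treatment = 0.31,
                                  pack_years = -0.002),
                         sigma2 = 0)
  cov <- list(treatment = 1, pack_years = 37.5, study_length = 168)
  got <- log(link_subject_params(sp2, cov, eta = -0.4)$theta)
  want <- log(0.01) - 0.4 + 0.2 * log(168) + 0.31 - 0.002 * 37.5
  expect_equal(got, want, tolerance = 1e-12)
  expect_gt(link_subject_params(sp2, cov, eta = -30)$theta, 0)
  # shape stays fixed unless shape frailty is switched on
  expect_equal(link_subject_params(sp2, cov, eta = 1)$alpha, 1.1)
  sp3 <- transition_spec("weibull", 0.01, 1.1, sigma2 = 0.1,
                         shape_frailty = TRUE)
  expect_equal(link_subject_params(sp3, list(study_length = 364),
                                   eta = 0.5)$alpha,
               1.1 * exp(0.5), tolerance = 1e-12)
  # missing covariate is a configuration error
  expect_error(link_subject_params(sp, list(study_length = 364)),
               "disease_stage")
})
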