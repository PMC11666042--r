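lorenz_theta <- matrix(c(10, 28, 8 / 3), 1)

test_that("lorenz rhs matches hand-computed values and rejects bad input", {
  expect_equal(as.numeric(lorenz_rhs(0, matrix(0, 1, 3), lorenz_theta)),
               c(0, 0, 0))
  expect_equal(as.numeric(lorenz_rhs(0, matrix(1, 1, 3), lorenz_theta)),
               c(0, 26, -5 / 3))
  expect_equal(as.numeric(lorenz_rhs(0, matrix(c(1, 0, 0), 1), lorenz_theta)),
               c(-10, 28, 0))
  expect_error(lorenz_rhs(0, matrix(c(NA, 0, 0), 1), lorenz_theta),
               "non-finite")
})

test_that("time-varying lorenz parameters match the benchmark formulas", {
  p0 <- lorenz_timevarying_params(0)
  expect_equal(unname(p0[1, "sigma"]), 10)
  expect_equal(unname(p0[1, "rho"]), 33.6)
  expect_equal(unname(lorenz_timevarying_params(0.25)[1, "sigma"]), 15)
  # sigma and rho are 1-periodic
  t <- seq(0, 2, length.out = 17)
  expect_equal(lorenz_timevarying_params(t), lorenz_timevarying_params(t + 1),
               tolerance = 1e-12)
})

test_that("mosquito rhs reproduces hand substitutions", {
  sys <- mosquito_system()
  stage0 <- matrix(0, 1, 10)
  th <- evaluate_params(sys, 91.25, use_truth = TRUE)  # tau = 20 C
  expect_equal(as.numeric(mosquito_rhs(91.25, stage0, th)), rep(0, 10))
  # only eggs present: dE = -(mu_E + f_E) E, dL = f_E E
  rates <- mosquito_default_rates()
  rates$f_E <- 0.5; rates$mu_E <- 0.1
  sys2 <- mosquito_system(rates)
  th2 <- evaluate_params(sys2, 0, use_truth = TRUE)
  uE <- stage0; uE[1, 1] <- 100
  d <- as.numeric(mosquito_rhs(0, uE, th2))
  expect_equal(d[1], -60)
  expect_equal(d[2], 50)
  expect_equal(d[3:10], rep(0, 8))
  # density dependence doubles m_L at L = kappa_L
  rates3 <- mosquito_default_rates()
  rates3$m_L <- 0.2; rates3$f_L <- 0.1
  sys3 <- mosquito_system(rates3)
  th3 <- evaluate_params(sys3, 0, use_truth = TRUE)
  uL <- stage0; uL[1, 2] <- rates3$kappa_L
  expect_equal(as.numeric(mosquito_rhs(0, uL, th3))[2],
               -(0.2 * 2 + 0.1) * rates3$kappa_L)
  # zero carrying capacity rejected
  expect_error(mosquito_system(modifyList(mosquito_default_rates(),
                                          list(kappa_L = 0))),
               "positive")
})

test_that("emergence exponent form is configurable", {
  rates <- mosquito_default_rates()
  sysP <- mosquito_system(rates, exponent_form = "P/kappaP")
  sys1 <- mosquito_system(rates, exponent_form = "1/kappaP")
  u <- matrix(0, 1, 10); u[1, 3] <- rates$kappa_P   # pupae at capacity
  th <- evaluate_params(sysP, 91.25, use_truth = TRUE)
  dP <- sysP$rhs(91.25, u, th)[1, 4]
  d1 <- sys1$rhs(91.25, u, th)[1, 4]
  # density-dependent form suppresses emergence more strongly at high P
  expect_lt(dP, d1)
})

test_that("temperature forcing matches the benchmark sine", {
  expect_equal(sine_temperature(0), 10)
  expect_equal(sine_temperature(91.25), 20)
  expect_equal(sine_temperature(365 * 3 / 4), 0)
})

test_that("evaluate_params resolves constants, formulas and models", {
  sys <- lorenz_system()
  th <- evaluate_params(sys, c(0, 1))
  expect_equal(unname(th[, 3]), c(8 / 3, 8 / 3))
  # temperature-dependent rate through the forcing
  sysm <- ode_system("toy", 1, function(t, u, th) -u,
                     list(param_spec("r", "known_function_of_time",
                                     function(t, tau) 0.01 * tau)),
                     forcing = sine_temperature)
  expect_equal(unname(evaluate_params(sysm, 91.25)[, 1]), 0.2)
  # empty spec -> zero-column matrix
  sys0 <- ode_system("bare", 1, function(t, u, th) -u)
  expect_equal(ncol(evaluate_params(sys0, c(0, 1))), 0L)
  # learnable without model errors; with values succeeds
  syse <- exponential_system(0.5, learn = TRUE)
  expect_error(evaluate_params(syse, 0), "no model")
  expect_equal(unname(evaluate_params(syse, 0, use_truth = TRUE)[, 1]), 0.5)
  expect_equal(unname(evaluate_params(syse, 0,
                                      models = list(theta = 0.3))[, 1]), 0.3)
})

test_that("non-negative initial states stay non-negative under integration", {
  sys <- mosquito_system()
  u0 <- c(1e6, 1e6, 1e5, 1e4, 1e4, 1e4, 1e4, 1e4, 1e4, 1e4)
  traj <- integrate_system(sys, u0, seq(0, 365, length.out = 120),
                           rtol = 1e-8, atol = 1e-8)
  expect_gt(min(traj$states), -1e-6)
})

test_that("system registry resolves names", {
  expect_s3_class(get_system("lorenz"), "ode_system")
  expect_equal(get_system("exponential", rate = 2)$param_spec[[1]]$value, 2)
  expect_error(get_system("pendulum"), "unknown system")
})
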