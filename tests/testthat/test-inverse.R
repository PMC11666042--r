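test_that("predict_params resolves constants, models and bounds", {
  sys <- exponential_system(0.5, learn = TRUE)
  spec <- normalization_spec(c(0, 2), Lu = 0, Uu = 1,
                             Ltheta = 0, Utheta = 20, adjust = FALSE)
  pm <- structure(list(kind = "constant", value = 0), class = "param_model")
  th <- predict_params(sys, list(theta = pm), c(0, 1, 2), spec)
  expect_equal(unname(th[, 1]), rep(10, 3))   # midpoint of (0, 20)
  expect_error(predict_params(sys, list(), 0, spec), "no model")
  # known constants need no model
  sysk <- lorenz_system()
  thk <- predict_params(sysk, list(), c(0, 1), spec)
  expect_equal(unname(thk[, "beta"]), rep(8 / 3, 2))
})

test_that("a network parameter model can represent a sine by regression", {
  spec <- normalization_spec(c(0, 2), Lu = 0, Uu = 1,
                             Ltheta = 4, Utheta = 16, adjust = FALSE)
  target_theta <- function(t) 5 * sin(2 * pi * t) + 10
  tp <- seq(-1, 1, length.out = 50)
  net <- regress_net(function(tp) {
    t <- denormalize_time(tp, spec)
    normalize_params(target_theta(t), spec, 1)
  }, tp, network_spec(4, 10), steps = 20000, lr = 1e-2, seed = 2,
     lr_final = 1e-3)
  tq <- seq(0, 2, length.out = 101)
  pred <- denormalize_params(
    as.numeric(net_forward(net, normalize_time(tq, spec))), spec, 1)
  expect_lt(max(abs(pred - target_theta(tq))), 0.1)
})

test_that("with no learnable parameters the inverse path is the forward path", {
  truth <- desk_truth()
  obs <- make_observations(truth, seq(0, 2, length.out = 5))
  cfg <- desk_config(phases = c(100L, 300L, 100L), eval_every = 200L)
  spec <- desk_spec(truth)
  f1 <- pinn_train(exponential_system(1), obs, c(0, 2), cfg,
                   norm_spec = spec, seed = 5)
  f2 <- recover_parameters(exponential_system(1), obs, c(0, 2), cfg,
                           norm_spec = spec, seed = 5)
  expect_identical(f1$traces$loss, f2$traces$loss)
  expect_identical(odepinn:::model_flatten(f1$model),
                   odepinn:::model_flatten(f2$model))
})

test_that("constant parameter gradients flow only through the scalar", {
  sys <- exponential_system(0.5, learn = TRUE)
  spec <- normalization_spec(c(0, 2), Lu = 0, Uu = 1,
                             Ltheta = 0.2, Utheta = 0.9)
  set.seed(6)
  model <- pinn_model(sys, network_spec(1, 4), network_spec(1, 4))
  op <- ode_pass(model, sys, spec, seq(-0.5, 0.5, length.out = 7),
                 weights_list = list(1))
  g <- op$grads[[1]]
  nu <- net_nparams(model$unet)
  expect_equal(length(g), nu + 1L)
  expect_true(g[nu + 1L] != 0)
  # and the data loss never touches the parameter scalar
  gd <- model_grad_flat(model,
                        data_pass(model$unet, 0, matrix(0.2),
                                  want_grad = TRUE)$gnet)
  expect_equal(gd[nu + 1L], 0)
})

test_that("gradient balancing improves parameter recovery on the chaotic
           inverse benchmark", {
  # time-varying sigma(t), rho(t) and constant beta recovered from 21
  # noiseless observations; balanced vs unbalanced at a matched desk budget
  sys <- lorenz_system(variant = "inverse")
  truth <- integrate_system(sys, c(1, 1, 1), seq(0, 2, length.out = 401))
  obs <- make_observations(truth, seq(0, 2, length.out = 21))
  b <- bounds_from_trajectory(truth)
  pb <- param_bounds_from_truth(sys, c(0, 2))
  spec <- normalization_spec(c(0, 2), b$Lu, b$Uu, pb$Ltheta, pb$Utheta)
  run <- function(bal) {
    cfg <- pinn_config(net = network_spec(2, 48),
                       param_net = network_spec(2, 10),
                       schedule = phase_schedule(0, 0, 8000,
                                                 eval_every = 1000),
                       balancing = balancing_config(0.9, 100, bal),
                       nf = 96, eval_grid = 300, log_every = 4000)
    fit <- recover_parameters(sys, obs, c(0, 2), cfg, norm_spec = spec,
                              seed = 1)
    rep_ <- param_error_report(fit)
    rep_$RMSE[nrow(rep_)]           # pooled theta RMSE
  }
  expect_lt(run(TRUE), run(FALSE))
})

test_that("recovery error shrinks with more observations", {
  sys <- exponential_system(0.5, learn = TRUE)
  truth <- integrate_system(sys, 1, seq(0, 2, length.out = 201))
  b <- bounds_from_trajectory(truth)
  pb <- param_bounds_from_truth(sys, c(0, 2))
  spec <- normalization_spec(c(0, 2), b$Lu, b$Uu, pb$Ltheta, pb$Utheta)
  cfg <- desk_config(phases = c(200L, 1500L, 800L), eval_every = 500L)
  err <- vapply(c(5L, 101L), function(n) {
    obs <- make_observations(truth, seq(0, 2, length.out = n))
    es <- vapply(1:2, function(s) {
      fit <- recover_parameters(sys, obs, c(0, 2), cfg, norm_spec = spec,
                                seed = s)
      abs(predict(fit, 1, what = "params")[1, "theta"] - 0.5)
    }, numeric(1))
    mean(es)
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.05)   # no degradation with 20x the data
})
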