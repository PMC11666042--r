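test_that("ablation presets map to the documented switch combinations", {
  expect_equal(ablation_preset("orig"),
               c(normalize = FALSE, balance = FALSE, causal = FALSE,
                 decompose = FALSE))
  expect_equal(ablation_preset("baseline"),
               c(normalize = TRUE, balance = FALSE, causal = FALSE,
                 decompose = FALSE))
  expect_equal(ablation_preset("grad_causal"),
               c(normalize = TRUE, balance = TRUE, causal = TRUE,
                 decompose = FALSE))
  expect_true(all(ablation_preset("grad_causal_domain")))
  expect_error(ablation_preset("super"), "unknown preset")
  # invalid combination rejected before any compute
  expect_error(experiment_config(problem = "inverse",
                                 preset = "grad_causal_domain"),
               "forward problems only")
})

test_that("experiments are deterministic given config and seed", {
  cfg <- experiment_config(system = "exponential", problem = "forward",
                           window = c(0, 2), preset = "grad_causal",
                           steps = c(100L, 400L, 100L),
                           net = network_spec(1, 8), nf = 16L,
                           eval_grid = 100L, sim_points = 101L)
  r1 <- run_experiment(cfg, seed = 3)
  r2 <- run_experiment(cfg, seed = 3)
  expect_identical(r1$state_errors, r2$state_errors)
  expect_identical(r1$losses, r2$losses)
  out1 <- file.path(tempdir(), "exp1"); out2 <- file.path(tempdir(), "exp2")
  write_json_summary <- function(res, d) odepinn:::write_experiment(res, d)
  write_json_summary(r1, out1); write_json_summary(r2, out2)
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
})

test_that("experiment artifacts include traces, errors and a checkpoint", {
  cfg <- experiment_config(system = "exponential", preset = "baseline",
                           steps = c(0L, 0L, 300L), net = network_spec(1, 8),
                           nf = 16L, eval_grid = 100L, sim_points = 101L)
  out <- file.path(tempdir(), "arts")
  res <- run_experiment(cfg, seed = 1, out_dir = out)
  expect_true(file.exists(file.path(out, "loss_trace.csv")))
  expect_true(file.exists(file.path(out, "state_errors.csv")))
  expect_true(file.exists(file.path(out, "checkpoint.json")))
  expect_true(file.exists(file.path(out, "summary.json")))
})

test_that("config yaml round-trips", {
  cfg <- experiment_config(system = "lorenz", problem = "inverse",
                           preset = "grad", steps = c(10L, 20L, 30L),
                           n_obs = 21L, alpha = 0.9, net = network_spec(2, 16))
  path <- tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  cfg2 <- read_experiment_config(path)
  expect_equal(cfg2$system, "lorenz")
  expect_equal(cfg2$preset, "grad")
  expect_equal(cfg2$steps, c(10L, 20L, 30L))
  expect_equal(cfg2$alpha, 0.9)
  expect_equal(cfg2$net$width, 16L)
  expect_equal(cfg2$switches, cfg$switches)
})

test_that("trajectories and observations round-trip through csv", {
  traj <- desk_truth(n = 21L)
  p <- tempfile(fileext = ".csv")
  write_trajectory(traj, p)
  tr2 <- read_trajectory(p, "exponential")
  expect_equal(tr2$times, traj$times)
  expect_equal(unname(tr2$states), unname(traj$states))
  obs <- make_observations(traj, c(0, 1, 2))
  po <- tempfile(fileext = ".csv")
  write_observations(obs, po)
  obs2 <- read_observations(po)
  expect_equal(obs2$Nu, 3L)
  expect_equal(unname(obs2$values), unname(obs$values))
})

test_that("checkpoints restore a fit's predictions exactly", {
  sys <- exponential_system(1)
  truth <- desk_truth()
  obs <- observation_set(0, matrix(1, 1, 1))
  cfg <- desk_config(phases = c(100L, 200L, 100L), eval_every = 200L)
  fit <- pinn_train(sys, obs, c(0, 2), cfg, norm_spec = desk_spec(truth),
                    seed = 8)
  p <- tempfile(fileext = ".json")
  save_checkpoint(fit, p)
  fit2 <- load_checkpoint(p, sys)
  tq <- seq(0, 2, length.out = 17)
  expect_equal(predict(fit2, tq), predict(fit, tq), tolerance = 1e-12)
})

test_that("subdomain sweep returns one row per S with linear step counts", {
  cfg <- experiment_config(system = "exponential", preset = "grad_causal",
                           window = c(0, 2), steps = c(50L, 200L, 50L),
                           net = network_spec(1, 8), nf = 16L,
                           eval_grid = 100L, sim_points = 101L, O = 0.1)
  sw <- subdomain_sweep(cfg, c(1L, 2L), seed = 1)
  expect_equal(sw$S, c(1L, 2L))
  expect_equal(sw$steps, c(300L, 600L))
  expect_true(all(is.finite(sw$rmse)))
})
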