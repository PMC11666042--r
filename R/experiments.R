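# Config-driven experiment runner: the ablation presets (which framework
# components are switched on), forward/inverse benchmark experiments, and the
# subdomain sweep.

ablation_presets <- list(
  orig               = c(normalize = FALSE, balance = FALSE, causal = FALSE, decompose = FALSE),
  baseline           = c(normalize = TRUE,  balance = FALSE, causal = FALSE, decompose = FALSE),
  grad               = c(normalize = TRUE,  balance = TRUE,  causal = FALSE, decompose = FALSE),
  causal             = c(normalize = TRUE,  balance = FALSE, causal = TRUE,  decompose = FALSE),
  grad_causal        = c(normalize = TRUE,  balance = TRUE,  causal = TRUE,  decompose = FALSE),
  grad_causal_domain = c(normalize = TRUE,  balance = TRUE,  causal = TRUE,  decompose = TRUE)
)

#' Ablation preset switches
#'
#' The named component combinations of the ablation study: `"orig"` (no
#' additions), `"baseline"` (normalization only), `"grad"` (+ gradient
#' balancing), `"causal"` (+ causal training), `"grad_causal"`,
#' `"grad_causal_domain"`. Switched-off behaviour: no normalization means
#' original scales; no balancing means all lambda fixed at 1; no causal
#' training means a single full-window phase; no decomposition means a single
#' domain.
#'
#' @param name Preset name.
#' @return Named logical vector `normalize, balance, causal, decompose`.
#' @export
ablation_preset <- function(name) {
  if (!name %in% names(ablation_presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(ablation_presets), collapse = ", "))
  ablation_presets[[name]]
}

#' Build an experiment configuration
#'
#' @param system System name (`"lorenz"`, `"mosquito"`, `"exponential"`).
#' @param problem `"forward"` or `"inverse"`.
#' @param window Time window.
#' @param preset Ablation preset name (see [ablation_preset()]).
#' @param steps Length-3 phase budget `(n1, N2, n3_max)`. When the preset has
#'   causal training off, all steps collapse into a single full-window phase
#'   of `sum(steps)`.
#' @param n_obs Observations for inverse problems (evenly spaced; forward
#'   problems use the single initial condition).
#' @param net,param_net Network specs.
#' @param alpha,N Balancing hyperparameters.
#' @param nf Collocation points per step.
#' @param lr Learning rate.
#' @param S,O,handoff_points Decomposition plan (used when the preset
#'   decomposes).
#' @param eval_grid,eval_every,patience Evaluation settings.
#' @param system_args Extra arguments to the system constructor.
#' @param sim_points Sample count of the ground-truth trajectory.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(system = "lorenz",
                              problem = c("forward", "inverse"),
                              window = c(0, 2), preset = "grad_causal",
                              steps = c(1000L, 20000L, 10000L),
                              n_obs = 21L,
                              net = network_spec(4L, 100L),
                              param_net = network_spec(4L, 10L),
                              alpha = 0.99, N = 100L, nf = 128L, lr = 1e-3,
                              S = 1L, O = 0, handoff_points = 100L,
                              eval_grid = 1000L, eval_every = 1000L,
                              patience = 100L,
                              system_args = list(), sim_points = 2001L) {
  problem <- match.arg(problem)
  sw <- ablation_preset(preset)
  if (sw[["decompose"]] && problem == "inverse")
    stop("domain decomposition is implemented for forward problems only")
  structure(list(system = system, problem = problem, window = window,
                 preset = preset, switches = sw, steps = as.integer(steps),
                 n_obs = as.integer(n_obs), net = net, param_net = param_net,
                 alpha = alpha, N = as.integer(N), nf = as.integer(nf),
                 lr = lr, S = as.integer(S), O = O,
                 handoff_points = as.integer(handoff_points),
                 eval_grid = as.integer(eval_grid),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience),
                 system_args = system_args,
                 sim_points = as.integer(sim_points)),
            class = "experiment_config")
}

# translate an experiment config into the trainer's config object
build_pinn_config <- function(config) {
  sw <- config$switches
  steps <- config$steps
  schedule <- if (sw[["causal"]]) {
    phase_schedule(steps[1], steps[2], steps[3],
                   eval_every = config$eval_every, patience = config$patience)
  } else {
    phase_schedule(0L, 0L, sum(steps),
                   eval_every = config$eval_every, patience = config$patience)
  }
  pinn_config(net = config$net, param_net = config$param_net,
              schedule = schedule,
              balancing = balancing_config(config$alpha, config$N,
                                           enabled = sw[["balance"]]),
              nf = config$nf, lr = config$lr, eval_grid = config$eval_grid,
              normalize = sw[["normalize"]])
}

build_system <- function(config) {
  args <- config$system_args
  args$u0 <- NULL   # initial state is not a constructor argument
  if (config$system == "lorenz" && config$problem == "inverse" &&
      is.null(args$variant)) args$variant <- "inverse"
  if (config$system == "exponential" && config$problem == "inverse" &&
      is.null(args$learn)) args$learn <- TRUE
  do.call(get_system, c(list(config$system), args))
}

#' Run a benchmark experiment
#'
#' Generates ground truth with the reference solver, builds the data condition
#' (a single initial state for forward problems, `n_obs` evenly spaced
#' noiseless observations for inverse ones), trains under the preset's
#' switches, and scores the result against the truth. Deterministic given
#' `(config, seed)`.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory for artifacts (traces, reports, summary
#'   JSON, checkpoint).
#' @return List with the fit, the truth trajectory, the state (and for inverse
#'   problems parameter) [error_report()]s, the final evaluation-loss
#'   decomposition (`L_data`, per-equation `L_f` at lambda = 1, `total`), and
#'   the config/seed manifest.
#' @export
run_experiment <- function(config, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  system <- build_system(config)
  sim_t <- seq(config$window[1], config$window[2],
               length.out = config$sim_points)
  # the generator never sees which parameters are learnable
  truth <- integrate_system(system, truth_initial_state(config, system), sim_t)
  obs <- if (config$problem == "forward") {
    observation_set(sim_t[1], truth$states[1L, , drop = FALSE])
  } else {
    make_observations(truth, seq(config$window[1], config$window[2],
                                 length.out = config$n_obs))
  }
  pc <- build_pinn_config(config)
  sw <- config$switches
  if (sw[["decompose"]]) {
    plan <- partition(config$window, config$S, config$O,
                      config$handoff_points)
    fit <- train_decomposed(system, plan, obs, config = pc, seed = seed,
                            truth = truth)
    eval_fit <- fit$fits[[length(fit$fits)]]
  } else {
    spec <- if (sw[["normalize"]]) {
      b <- bounds_from_trajectory(truth)
      pb <- if (length(learnable_params(system)))
        param_bounds_from_truth(system, config$window)
      else list(Ltheta = NULL, Utheta = NULL)
      normalization_spec(config$window, b$Lu, b$Uu, pb$Ltheta, pb$Utheta)
    }
    fit <- pinn_train(system, obs, config$window, config = pc,
                      norm_spec = spec, seed = seed)
    eval_fit <- fit
  }
  state_rep <- state_error_report(fit, truth)
  param_rep <- if (config$problem == "inverse")
    param_error_report(eval_fit)
  losses <- loss_components(eval_fit)
  out <- list(fit = fit, truth = truth, state_errors = state_rep,
              param_errors = param_rep, losses = losses,
              manifest = list(config = unclass(config), seed = seed,
                              package_version = as.character(
                                utils::packageVersion("odepinn"))))
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  invisible(out)
}

# final evaluation-loss decomposition at lambda = 1 on the fixed grid
loss_components <- function(fit, n_grid = 1000L) {
  spec <- fit$norm_spec
  tpw <- normalize_time(fit$window, spec)
  grid_tp <- seq(tpw[1], tpw[2], length.out = n_grid)
  ld <- data_pass(fit$model$unet, normalize_time(fit$obs$times, spec),
                  normalize_state(fit$obs$values, spec))$loss
  lf <- ode_pass(fit$model, fit$system, spec, grid_tp)$Lf
  list(L_data = ld, L_f = lf, total = total_loss(ld, lf))
}

#' Subdomain-count sweep
#'
#' Runs the decomposed forward experiment once per value of `S` and reports
#' the accuracy/cost trade-off. `S = 1` is a plain single-domain run.
#'
#' @param config A forward [experiment_config()] (its `S` is overridden).
#' @param S_values Integer vector of subdomain counts.
#' @param seed Seed shared by the runs.
#' @return data.frame with columns `S`, `steps` (total training steps) and
#'   `rmse` (stitched prediction vs truth on a dense grid).
#' @export
subdomain_sweep <- function(config, S_values, seed = 1L) {
  stopifnot(config$problem == "forward")
  rows <- lapply(S_values, function(S) {
    cfg <- config
    cfg$S <- as.integer(S)
    cfg$switches[["decompose"]] <- TRUE
    if (S == 1L) cfg$O <- 0
    res <- run_experiment(cfg, seed = seed)
    data.frame(S = S, steps = S * sum(config$steps),
               rmse = res$state_errors$RMSE[nrow(res$state_errors)])
  })
  do.call(rbind, rows)
}

truth_initial_state <- function(config, system) {
  if (!is.null(config$system_args$u0)) return(config$system_args$u0)
  switch(config$system,
         lorenz = c(1, 1, 1),
         exponential = 1,
         mosquito = c(1e6, 1e6, 1e5, 1e4, 1e4, 1e4, 1e4, 1e4, 1e4, 1e4),
         stop("no default initial state for system '", config$system, "'"))
}
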