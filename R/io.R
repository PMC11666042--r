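# Plain-text serialization: trajectories and observations as CSV, checkpoints
# and run summaries as JSON, experiment configurations as YAML.

#' Write / read a trajectory as CSV
#'
#' Columns `t, <state_1>, ..., <state_V>`.
#'
#' @param traj An `ode_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param system_name Stored in the returned object.
#' @export
read_trajectory <- function(path, system_name = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(list(times = df$t,
                 states = as.matrix(df[, -1L, drop = FALSE]),
                 system = system_name, rtol = NA_real_, atol = NA_real_),
            class = "ode_trajectory")
}

#' Write / read an observation set as CSV
#'
#' @param obs An [observation_set()].
#' @param path File path.
#' @export
write_observations <- function(obs, path) {
  df <- data.frame(t = obs$times, obs$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  observation_set(df$t, as.matrix(df[, -1L, drop = FALSE]))
}

#' Save / load a fitted PINN checkpoint (JSON)
#'
#' The checkpoint stores the flat weight vector, the architecture, the
#' normalization spec and the window, so predictions are reproducible.
#' Loading needs the matching [ode_system()] (systems hold functions, which a
#' text checkpoint cannot carry).
#'
#' @param fit A `pinn_fit`.
#' @param path File path.
#' @export
save_checkpoint <- function(fit, path) {
  sp <- fit$norm_spec
  ck <- list(
    package = "odepinn", format = 1L,
    system = fit$system$name, window = fit$window, seed = fit$seed,
    net = unclass(fit$model$unet$spec),
    state_dim = fit$system$state_dim,
    param_models = lapply(fit$model$pmodels, function(pm)
      list(kind = pm$kind,
           net = if (pm$kind == "network") unclass(pm$net$spec))),
    norm_spec = list(Tmin = sp$Tmin, Tmax = sp$Tmax, Lu = sp$Lu, Uu = sp$Uu,
                     Ltheta = sp$Ltheta, Utheta = sp$Utheta),
    weights = model_flatten(fit$model),
    best_eval_loss = fit$best_eval_loss
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param system The [ode_system()] the checkpoint was trained on.
#' @export
load_checkpoint <- function(path, system) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ck$system, system$name))
    warning("checkpoint was saved for system '", ck$system, "'")
  spec <- normalization_spec(unlist(ck$window),
                             Lu = ck$norm_spec$Lu, Uu = ck$norm_spec$Uu,
                             adjust = FALSE)
  spec$Tmin <- ck$norm_spec$Tmin; spec$Tmax <- ck$norm_spec$Tmax
  spec$Ltheta <- ck$norm_spec$Ltheta; spec$Utheta <- ck$norm_spec$Utheta
  ns <- network_spec(ck$net$n_hidden, ck$net$width, ck$net$activation)
  model <- list(unet = mlp_init(ns, out_dim = ck$state_dim),
                pmodels = list(), learn_idx = learnable_params(system))
  for (nm in names(ck$param_models)) {
    pmck <- ck$param_models[[nm]]
    model$pmodels[[nm]] <- if (identical(pmck$kind, "constant")) {
      structure(list(kind = "constant", value = 0), class = "param_model")
    } else {
      pns <- network_spec(pmck$net$n_hidden, pmck$net$width,
                          pmck$net$activation)
      structure(list(kind = "network", net = mlp_init(pns, out_dim = 1L)),
                class = "param_model")
    }
  }
  model <- model_unflatten(model, ck$weights)
  structure(list(model = model, system = system, norm_spec = spec,
                 config = NULL, window = unlist(ck$window), obs = NULL,
                 seed = ck$seed, best_eval_loss = ck$best_eval_loss,
                 best_step = NA_integer_, stopped_step = NA_integer_,
                 diverged = FALSE, traces = NULL),
            class = "pinn_fit")
}

# artifact bundle of run_experiment
write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(res$truth, file.path(out_dir, "truth.csv"))
  fit <- res$fit
  if (inherits(fit, "pinn_decomposed")) {
    for (s in seq_along(fit$fits)) {
      sd <- file.path(out_dir, sprintf("sub_%02d", s))
      dir.create(sd, showWarnings = FALSE)
      write_fit_artifacts(fit$fits[[s]], sd)
    }
    times <- seq(fit$window[1], fit$window[2], length.out = 512L)
    utils::write.csv(data.frame(t = times, predict(fit, times),
                                check.names = FALSE),
                     file.path(out_dir, "stitched.csv"), row.names = FALSE)
  } else {
    write_fit_artifacts(fit, out_dir)
  }
  utils::write.csv(res$state_errors, file.path(out_dir, "state_errors.csv"),
                   row.names = FALSE)
  if (!is.null(res$param_errors))
    utils::write.csv(res$param_errors, file.path(out_dir, "param_errors.csv"),
                     row.names = FALSE)
  summary <- list(manifest = res$manifest,
                  losses = res$losses,
                  overall_rmse =
                    res$state_errors$RMSE[nrow(res$state_errors)])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}

write_fit_artifacts <- function(fit, dir) {
  if (!is.null(fit$traces$loss) && nrow(fit$traces$loss))
    utils::write.csv(fit$traces$loss, file.path(dir, "loss_trace.csv"),
                     row.names = FALSE)
  if (!is.null(fit$traces$lambda))
    utils::write.csv(fit$traces$lambda, file.path(dir, "lambda_trace.csv"),
                     row.names = FALSE)
  save_checkpoint(fit, file.path(dir, "checkpoint.json"))
}

#' Read / write an experiment configuration (YAML)
#'
#' @param path File path.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    system = y$system %||% "lorenz",
    problem = y$problem %||% "forward",
    window = as.numeric(y$window %||% c(0, 2)),
    preset = y$preset %||% "grad_causal",
    steps = as.integer(y$steps %||% c(1000, 20000, 10000))
  )
  if (!is.null(y$net))
    args$net <- network_spec(y$net$n_hidden, y$net$width,
                             y$net$activation %||% "gelu")
  if (!is.null(y$param_net))
    args$param_net <- network_spec(y$param_net$n_hidden, y$param_net$width,
                                   y$param_net$activation %||% "gelu")
  for (nm in c("n_obs", "N", "nf", "S", "handoff_points", "eval_grid",
               "eval_every", "patience", "sim_points"))
    if (!is.null(y[[nm]])) args[[nm]] <- as.integer(y[[nm]])
  for (nm in c("alpha", "lr", "O"))
    if (!is.null(y[[nm]])) args[[nm]] <- as.numeric(y[[nm]])
  if (!is.null(y$system_args)) args$system_args <- y$system_args
  do.call(experiment_config, args)
}

#' @rdname read_experiment_config
#' @param config An [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  y <- unclass(config)
  y$switches <- NULL
  y$net <- unclass(config$net)
  y$param_net <- unclass(config$param_net)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
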