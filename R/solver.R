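# Reference integrator: high-accuracy numerical ground truth for every
# experiment, and the synthetic observation generator.

#' Integrate an ODE system to high accuracy
#'
#' Adaptive Dormand--Prince 4(5) integration (deSolve's `"ode45"` method) of a
#' system from an initial state, sampled at the requested times. This is the
#' oracle every PINN result is scored against; tolerances default to 1e-9 so
#' that desk-scale error targets are solver-stable.
#'
#' @param system An [ode_system()].
#' @param u0 Initial state (length `V`), applying at `eval_times[1]`.
#' @param eval_times Strictly increasing times at which to report the solution.
#' @param rtol,atol Relative/absolute tolerances.
#' @return An `ode_trajectory`: list with `times`, `states` (`n x V` matrix),
#'   `system` (name) and the tolerances used.
#' @export
integrate_system <- function(system, u0, eval_times, rtol = 1e-9, atol = 1e-9) {
  stopifnot(length(u0) == system$state_dim, length(eval_times) >= 2L)
  if (any(diff(eval_times) <= 0)) stop("eval_times must be strictly increasing")
  derivs <- function(t, y, parms) {
    theta <- evaluate_params(system, t, use_truth = TRUE)
    list(as.numeric(eval_rhs(system, t, matrix(y, 1L), theta)))
  }
  sol <- deSolve::ode(y = u0, times = eval_times, func = derivs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) < length(eval_times) || !all(is.finite(sol)))
    stop("integration of '", system$name, "' failed near t = ",
         sol[nrow(sol), 1L])
  states <- unname(sol[, -1L, drop = FALSE])
  colnames(states) <- system$state_names
  structure(list(times = eval_times, states = states, system = system$name,
                 rtol = rtol, atol = atol),
            class = "ode_trajectory")
}

#' Sample synthetic observations from a trajectory
#'
#' Linear interpolation of the trajectory at the requested times plus optional
#' i.i.d. Gaussian noise (the benchmark experiments use noiseless data, the
#' default).
#'
#' @param traj An `ode_trajectory`.
#' @param times Observation times, inside the trajectory's range.
#' @param noise_sd Per-dimension noise standard deviation (recycled); default 0.
#' @param seed Optional seed for the noise draw.
#' @return An `observation_set`: `times`, `values` (`Nu x V`), `Nu`, `noise_sd`.
#' @export
make_observations <- function(traj, times, noise_sd = 0, seed = NULL) {
  rng <- range(traj$times)
  if (any(times < rng[1]) || any(times > rng[2]))
    stop("requested observation times outside the trajectory range")
  V <- ncol(traj$states)
  vals <- vapply(seq_len(V), function(k)
    stats::approx(traj$times, traj$states[, k], xout = times)$y,
    numeric(length(times)))
  vals <- matrix(vals, nrow = length(times), ncol = V,
                 dimnames = list(NULL, colnames(traj$states)))
  noise_sd <- rep(noise_sd, length.out = V)
  if (any(noise_sd > 0)) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + matrix(stats::rnorm(length(times) * V), ncol = V) *
      rep(noise_sd, each = length(times))
  }
  observation_set(times, vals, noise_sd = noise_sd)
}

#' Construct an observation set
#'
#' @param times Observation times.
#' @param values `Nu x V` matrix (a vector is treated as one column).
#' @param noise_sd Per-dimension noise sd recorded with the set.
#' @export
observation_set <- function(times, values, noise_sd = 0) {
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  stopifnot(length(times) == nrow(values))
  structure(list(times = times, values = values, Nu = length(times),
                 noise_sd = noise_sd),
            class = "observation_set")
}

#' @export
print.ode_trajectory <- function(x, ...) {
  cat("<ode_trajectory> ", x$system, ": ", length(x$times), " samples on [",
      min(x$times), ", ", max(x$times), "], V = ", ncol(x$states), "\n", sep = "")
  invisible(x)
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> Nu = ", x$Nu, ", V = ", ncol(x$values),
      ", t in [", min(x$times), ", ", max(x$times), "]\n", sep = "")
  invisible(x)
}
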