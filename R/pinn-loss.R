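# The three loss ingredients in normalized coordinates: data loss, per-equation
# ODE residual losses, and collocation sampling; plus the gradient passes the
# trainer and the balancing algorithm share.
#
# Normalized residual of equation i at collocation time t':
#   r_i = dU_i/dt'  -  (2 / (Uu_i - Lu_i)) * ((Tmax - Tmin) / 2) * f_i(t, u, theta)
# The state chain factor 2/(Uu-Lu) rescales f to normalized state units; the
# time chain factor (Tmax-Tmin)/2 converts d/dt to d/dt'. For a window of
# width 2 the time factor is 1 and the textbook normalized residual is
# recovered.

# ---- model container ---------------------------------------------------------

# A "pinn_model" bundles the solution network and the (possibly empty) named
# list of parameter models; all trainable scalars are exposed as one flat
# vector for the optimizer.
pinn_model <- function(system, net_spec, param_net_spec = network_spec(4L, 10L)) {
  unet <- mlp_init(net_spec, out_dim = system$state_dim)
  li <- learnable_params(system)
  pmodels <- list()
  for (p in li) {
    ps <- system$param_spec[[p]]
    pmodels[[ps$name]] <- param_model(
      if (ps$kind == "learn_constant") "constant" else "network",
      net_spec = param_net_spec)
  }
  list(unet = unet, pmodels = pmodels, learn_idx = li)
}

model_nparams <- function(model) {
  net_nparams(model$unet) + sum(vapply(model$pmodels, pm_nparams, 1L))
}

model_flatten <- function(model) {
  c(net_flatten(model$unet),
    unlist(lapply(model$pmodels, pm_flatten), use.names = FALSE))
}

model_unflatten <- function(model, v) {
  nu <- net_nparams(model$unet)
  model$unet <- net_unflatten(model$unet, v[seq_len(nu)])
  pos <- nu
  for (nm in names(model$pmodels)) {
    np <- pm_nparams(model$pmodels[[nm]])
    model$pmodels[[nm]] <- pm_unflatten(model$pmodels[[nm]],
                                        v[pos + seq_len(np)])
    pos <- pos + np
  }
  model
}

# assemble a full-length flat gradient from structured pieces (zeros where a
# loss has no dependence)
model_grad_flat <- function(model, gunet = NULL, gpmodels = NULL) {
  gu <- if (is.null(gunet)) numeric(net_nparams(model$unet))
        else net_flatten(gunet)
  gps <- lapply(names(model$pmodels), function(nm) {
    g <- gpmodels[[nm]]
    if (is.null(g)) numeric(pm_nparams(model$pmodels[[nm]]))
    else if (is.numeric(g)) g
    else net_flatten(g)
  })
  c(gu, unlist(gps, use.names = FALSE))
}

# ---- collocation -------------------------------------------------------------

#' Sample collocation (residual) points
#'
#' i.i.d. uniform draws on an interval of normalized time. With a `seed` the
#' draw is reproducible and the caller's RNG stream is left untouched.
#'
#' @param n Number of points.
#' @param interval Length-2 interval `(a, b)` with `a < b`.
#' @param seed Optional integer seed.
#' @export
sample_collocation <- function(n, interval, seed = NULL) {
  stopifnot(n >= 1L, length(interval) == 2L)
  if (interval[1] >= interval[2]) stop("collocation interval must have a < b")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stats::runif(n, interval[1], interval[2])
}

# ---- data loss ---------------------------------------------------------------

# internal: loss and (optionally) gradient of the data term at normalized
# observations. Mean squared error over records AND state dimensions.
data_pass <- function(unet, obs_tp, obs_up, want_grad = FALSE) {
  fw <- mlp_eval(unet, obs_tp, tangent = FALSE, keep_cache = want_grad)
  R <- fw$U - obs_up
  loss <- mean(R * R)
  g <- NULL
  if (want_grad) g <- mlp_backward(unet, fw$cache, gU = 2 * R / length(R))
  list(loss = loss, gnet = g)
}

#' Data loss of a solution network against observations
#'
#' Mean squared error between the network outputs at the normalized
#' observation times and the normalized observed states, averaged over records
#' and state dimensions.
#'
#' @param net Solution network (`mlp_net`).
#' @param obs An [observation_set()] in original units.
#' @param spec A [normalization_spec()].
#' @export
data_loss <- function(net, obs, spec) {
  if (obs$Nu == 0L) stop("empty observation set")
  data_pass(net, normalize_time(obs$times, spec),
            normalize_state(obs$values, spec))$loss
}

# ---- ODE residual loss -------------------------------------------------------

# central finite-difference Jacobians of the rhs wrt state columns (and wrt the
# learnable parameter columns); vectorized over points. Returns lists of n x F
# matrices.
fd_jacobians <- function(system, t, u, theta, learn_idx) {
  n <- nrow(u); V <- ncol(u)
  Ju <- vector("list", V)
  for (k in seq_len(V)) {
    h <- 1e-6 * pmax(1, abs(u[, k]))
    up <- u; up[, k] <- u[, k] + h
    um <- u; um[, k] <- u[, k] - h
    Ju[[k]] <- (eval_rhs(system, t, up, theta) -
                eval_rhs(system, t, um, theta)) / (2 * h)
  }
  Jth <- list()
  for (p in learn_idx) {
    h <- 1e-6 * pmax(1, abs(theta[, p]))
    tp_ <- theta; tp_[, p] <- theta[, p] + h
    tm_ <- theta; tm_[, p] <- theta[, p] - h
    Jth[[system$param_spec[[p]]$name]] <-
      (eval_rhs(system, t, u, tp_) - eval_rhs(system, t, u, tm_)) / (2 * h)
  }
  list(Ju = Ju, Jth = Jth)
}

# internal workhorse: per-equation residual losses at collocation points, and
# flat gradients for each requested weighting of the equations.
#   weights_list: list of length-F weight vectors w; for each, the gradient of
#   sum_i w_i * L_f(i) over all model parameters is returned.
ode_pass <- function(model, system, spec, tp, weights_list = NULL) {
  n <- length(tp)
  V <- system$state_dim
  want_grad <- length(weights_list) > 0L
  fw <- mlp_eval(model$unet, tp, tangent = TRUE, keep_cache = want_grad)
  t <- denormalize_time(tp, spec)
  u <- denormalize_state(fw$U, spec)
  # assemble theta: known from formulas, learnable from models
  pvals <- list(); pcaches <- list()
  for (p in model$learn_idx) {
    nm <- system$param_spec[[p]]$name
    pe <- pm_eval(model$pmodels[[nm]], tp, keep_cache = want_grad)
    pvals[[nm]] <- denormalize_params(as.numeric(pe$U), spec, p)
    pcaches[[nm]] <- pe$cache
  }
  theta <- evaluate_params(system, t, models = pvals)
  f <- eval_rhs(system, t, u, theta)
  cfac <- residual_factor(spec)
  r <- fw$dU - f * rep(cfac, each = n)
  Lf <- colMeans(r * r)
  out <- list(Lf = Lf)
  if (want_grad) {
    J <- fd_jacobians(system, t, u, theta, model$learn_idx)
    half_u <- (spec$Uu - spec$Lu) / 2
    out$grads <- lapply(weights_list, function(w) {
      sc <- 2 * w / n
      gdU <- r * rep(sc, each = n)                  # d loss / d (dU/dt')
      gF <- -gdU * rep(cfac, each = n)              # d loss / d f_i
      gU <- matrix(0, n, V)
      for (k in seq_len(V))
        gU[, k] <- rowSums(gF * J$Ju[[k]]) * half_u[k]
      gunet <- mlp_backward(model$unet, fw$cache, gU = gU, gdU = gdU)
      gpm <- list()
      for (p in model$learn_idx) {
        nm <- system$param_spec[[p]]$name
        gth <- rowSums(gF * J$Jth[[nm]]) *
          (spec$Utheta[p] - spec$Ltheta[p]) / 2
        gpm[[nm]] <- pm_backward(model$pmodels[[nm]], pcaches[[nm]],
                                 matrix(gth, ncol = 1L))
      }
      model_grad_flat(model, gunet, gpm)
    })
  }
  out
}

#' Per-equation ODE residual losses
#'
#' Mean squared normalized residual of each equation at the given collocation
#' points: the network's exact time derivative minus the rescaled right-hand
#' side evaluated at the denormalized network state and parameters.
#'
#' @param net Solution network.
#' @param param_models Named list of [param_model()]s for learnable parameters
#'   (empty list for a forward problem).
#' @param system An [ode_system()].
#' @param spec A [normalization_spec()].
#' @param points Collocation points in normalized time.
#' @return Numeric vector of length `F` (one loss per equation).
#' @export
ode_loss <- function(net, param_models, system, spec, points) {
  model <- list(unet = net, pmodels = param_models,
                learn_idx = learnable_params(system))
  ode_pass(model, system, spec, points)$Lf
}

#' Combine the loss terms
#'
#' `total = L_data + (1/F) * sum_i lambda_i * L_f(i)`.
#'
#' @param L_data Scalar data loss.
#' @param L_f Length-`F` vector of equation losses.
#' @param lambdas Length-`F` weight vector (data weight is fixed at 1).
#' @export
total_loss <- function(L_data, L_f, lambdas = rep(1, length(L_f))) {
  stopifnot(length(lambdas) == length(L_f))
  L_data + sum(lambdas * L_f) / length(L_f)
}

#' Normalized residuals of a reference trajectory
#'
#' Consistency check of the normalization maps: the trajectory is converted to
#' normalized coordinates, its normalized time derivative is estimated by
#' central finite differences of the normalized interpolant (independent of the
#' right-hand side), and the normalized residual is formed. For an exact
#' solution the residuals vanish up to finite-difference and solver error.
#'
#' @param system An [ode_system()].
#' @param traj An `ode_trajectory` of the true solution.
#' @param spec A [normalization_spec()].
#' @param times Times at which to evaluate the residual (interior of the
#'   trajectory range).
#' @param h Finite-difference half-step in original time units.
#' @return `n x F` matrix of residuals.
#' @export
trajectory_residuals <- function(system, traj, spec, times, h = 1e-4) {
  V <- ncol(traj$states)
  interp <- function(tt) vapply(seq_len(V), function(k)
    stats::approx(traj$times, traj$states[, k], xout = tt)$y,
    numeric(length(tt)))
  up <- normalize_state(matrix(interp(times + h), ncol = V), spec)
  um <- normalize_state(matrix(interp(times - h), ncol = V), spec)
  hp <- 2 * h * 2 / (spec$Tmax - spec$Tmin)   # step in normalized time
  dudtp <- (up - um) / hp
  u <- matrix(interp(times), ncol = V)
  theta <- evaluate_params(system, times, use_truth = TRUE)
  f <- eval_rhs(system, times, u, theta)
  dudtp - f * rep(residual_factor(spec), each = length(times))
}
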