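# Time-domain decomposition: equal non-overlapping core subdomains that tile
# the window, extended training domains with one-sided overlap O, sequential
# training with value handoff at the interfaces, and the stitched predictor
# that answers each query from the network whose core contains it.

#' Partition a time window into subdomains
#'
#' Cores `[T_{s-1}, T_s]` of equal width tile the window; each training domain
#' is the core extended by the one-sided overlap `O` on both ends and clipped
#' at the window boundaries.
#'
#' @param window Length-2 time window.
#' @param S Subdomain count.
#' @param O Overlap extension (same units as time); must be smaller than the
#'   core width.
#' @param handoff_points Generated data points per interface (default 100).
#' @return A `decomposition_plan` with `boundaries` (length `S + 1`),
#'   `extended` (`S x 2` matrix), `O` and `handoff_points`.
#' @export
partition <- function(window, S, O = 0, handoff_points = 100L) {
  stopifnot(length(window) == 2L, window[2] > window[1], S >= 1L, O >= 0)
  core <- diff(window) / S
  if (O >= core) stop("overlap O must be smaller than the core width ",
                      signif(core, 4))
  boundaries <- seq(window[1], window[2], length.out = S + 1L)
  extended <- cbind(pmax(boundaries[-(S + 1L)] - O, window[1]),
                    pmin(boundaries[-1L] + O, window[2]))
  structure(list(window = window, S = as.integer(S), O = O,
                 boundaries = boundaries, extended = extended,
                 handoff_points = as.integer(handoff_points)),
            class = "decomposition_plan")
}

#' Generate handoff data from a trained subdomain
#'
#' Evaluates the previous subdomain's fit at evenly spaced times on the
#' interface (the overlap `[T_{s-1}, T_{s-1} + O]` at the start of the next
#' core) and returns the denormalized predictions as the next subdomain's data
#' condition. The first subdomain instead uses the user-provided initial data.
#'
#' @param fit The previous subdomain's `pinn_fit`.
#' @param interface Length-2 interval, inside the previous extended domain.
#' @param n_points Number of evenly spaced handoff points.
#' @return An [observation_set()].
#' @export
handoff_data <- function(fit, interface, n_points = 100L) {
  if (interface[1] < fit$window[1] - 1e-9 ||
      interface[2] > fit$window[2] + 1e-9)
    stop("interface lies outside the previous subdomain's window")
  times <- seq(interface[1], interface[2], length.out = n_points)
  observation_set(times, predict(fit, times))
}

#' Train a decomposed PINN
#'
#' Subdomains are trained sequentially, each as an independent PINN problem on
#' its extended domain with its own normalization (state bounds from the
#' ground-truth slice when `truth` is supplied, otherwise from the incoming
#' data values widened by 20%) and the full three-phase schedule. Subdomain
#' `s` trains on the handoff data generated by subdomain `s - 1`; the first
#' uses `init_obs`.
#'
#' @param system An [ode_system()].
#' @param plan A [partition()] plan.
#' @param init_obs [observation_set()] with the user initial condition(s).
#' @param config A [pinn_config()] shared by all subdomains.
#' @param seed Master seed; subdomain `s` trains with `seed + s - 1`.
#' @param truth Optional reference `ode_trajectory` used for per-subdomain
#'   bounds (as the forward benchmarks do).
#' @return A `pinn_decomposed` fit; `predict()` stitches the subdomain
#'   networks.
#' @export
train_decomposed <- function(system, plan, init_obs, config = pinn_config(),
                             seed = 1L, truth = NULL) {
  fits <- vector("list", plan$S)
  obs_s <- init_obs
  for (s in seq_len(plan$S)) {
    ext <- plan$extended[s, ]
    spec <- NULL
    if (config$normalize) {
      b <- if (!is.null(truth)) bounds_from_trajectory(truth, window = ext)
           else {
             v <- obs_s$values
             list(Lu = apply(v, 2L, min) - 0.2 * pmax(abs(apply(v, 2L, min)), 1e-6),
                  Uu = apply(v, 2L, max) + 0.2 * pmax(abs(apply(v, 2L, max)), 1e-6))
           }
      spec <- normalization_spec(ext, Lu = b$Lu, Uu = b$Uu)
    }
    fit <- pinn_train(system, obs_s, ext, config = config, norm_spec = spec,
                      seed = seed + s - 1L)
    if (fit$diverged)
      stop("subdomain ", s, " diverged; ", s - 1L,
           " subdomain(s) completed before the failure")
    fits[[s]] <- fit
    if (s < plan$S) {
      iface <- c(plan$boundaries[s + 1L],
                 min(plan$boundaries[s + 1L] + plan$O, ext[2]))
      if (plan$O <= 0) iface <- rep(plan$boundaries[s + 1L], 2L) + c(0, 1e-12)
      obs_s <- handoff_data(fit, iface, plan$handoff_points)
    }
  }
  structure(list(fits = fits, plan = plan, system = system,
                 window = plan$window, seed = seed, config = config),
            class = "pinn_decomposed")
}

#' Stitched prediction from per-subdomain networks
#'
#' Each query time is answered by the network whose core subdomain contains it
#' (cores are left-closed/right-open; the last core is right-closed).
#'
#' @param object A `pinn_decomposed`.
#' @param times Query times inside the window.
#' @param ... Unused.
#' @export
predict.pinn_decomposed <- function(object, times, ...) {
  plan <- object$plan
  if (any(times < plan$window[1] - 1e-12) ||
      any(times > plan$window[2] + 1e-12))
    stop("query times outside the decomposition window")
  s_idx <- findInterval(times, plan$boundaries)
  s_idx[s_idx > plan$S] <- plan$S     # right-closed last core
  s_idx[s_idx < 1L] <- 1L
  out <- matrix(NA_real_, length(times), object$system$state_dim,
                dimnames = list(NULL, object$system$state_names))
  for (s in unique(s_idx)) {
    sel <- s_idx == s
    out[sel, ] <- predict(object$fits[[s]], times[sel])
  }
  out
}

#' Interface continuity diagnostics
#'
#' For each interior boundary, the jump between the two adjoining subdomain
#' predictions and the RMSE of the later subdomain's fit to its handoff data
#' (value enforcement at the interface bounds the jump).
#'
#' @param object A `pinn_decomposed`.
#' @return data.frame with columns `boundary`, `jump` (max over dimensions of
#'   the absolute prediction gap) and `handoff_rmse`.
#' @export
interface_jumps <- function(object) {
  plan <- object$plan
  if (plan$S < 2L) return(data.frame(boundary = numeric(0), jump = numeric(0),
                                     handoff_rmse = numeric(0)))
  rows <- lapply(seq_len(plan$S - 1L), function(s) {
    tb <- plan$boundaries[s + 1L]
    left <- predict(object$fits[[s]], tb)
    right <- predict(object$fits[[s + 1L]], tb)
    ho <- object$fits[[s + 1L]]$obs
    fitted <- predict(object$fits[[s + 1L]], ho$times)
    data.frame(boundary = tb, jump = max(abs(left - right)),
               handoff_rmse = rmse(fitted, ho$values))
  })
  do.call(rbind, rows)
}

#' @export
print.pinn_decomposed <- function(x, ...) {
  cat("<pinn_decomposed> ", x$system$name, ", S = ", x$plan$S,
      " subdomains on [", x$window[1], ", ", x$window[2], "], O = ",
      x$plan$O, "\n", sep = "")
  invisible(x)
}
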