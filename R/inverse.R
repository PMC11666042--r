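# Inverse problems: joint recovery of the solution surrogate and the unknown
# parameters, plus scoring of the recovered parameters against their true
# values.

#' Recover unknown ODE parameters from observations
#'
#' Thin wrapper around [pinn_train()]: the system's `learn_*` parameter
#' entries get trainable models (a single normalized scalar for constants, a
#' small time-input network otherwise) which are trained jointly with the
#' solution surrogate under the full framework. With no learnable parameters
#' this is exactly the forward problem.
#'
#' @inheritParams pinn_train
#' @return A `pinn_fit`; use [predict.pinn_fit()] with `what = "params"` for
#'   the recovered parameter curves and [param_error_report()] to score them.
#' @export
recover_parameters <- function(system, obs, window, config = pinn_config(),
                               norm_spec = NULL, seed = 1L) {
  if (obs$Nu <= 1L && length(learnable_params(system)))
    stop("inverse problems need more than one observation")
  pinn_train(system, obs, window, config = config, norm_spec = norm_spec,
             seed = seed)
}

#' Score recovered parameters against their true values
#'
#' Evaluates the trained parameter models and the stored true
#' values/formulas on a dense grid of the fit window and reports the error
#' metrics per parameter plus pooled overall.
#'
#' @param fit A `pinn_fit` with learnable parameters.
#' @param times Evaluation times; default 512 uniform points over the window.
#' @return An [error_report()] data frame over the learnable parameters, with
#'   attribute `"curves"` carrying `(t, predicted, true)` for plotting/export.
#' @export
param_error_report <- function(fit, times = NULL) {
  sys <- fit$system
  li <- learnable_params(sys)
  if (!length(li)) stop("fit has no learnable parameters")
  if (is.null(times))
    times <- seq(fit$window[1], fit$window[2], length.out = 512L)
  pred <- predict(fit, times, what = "params")[, li, drop = FALSE]
  truth <- evaluate_params(sys, times, use_truth = TRUE)[, li, drop = FALSE]
  nms <- param_names(sys)[li]
  rep_ <- error_report(pred, truth, names = nms)
  curves <- data.frame(t = times, pred, truth)
  names(curves) <- c("t", nms, paste0(nms, "_true"))
  attr(rep_, "curves") <- curves
  rep_
}

#' Score the fitted state against a reference trajectory
#'
#' @param fit A `pinn_fit` (or decomposed fit; anything with a `predict`
#'   method returning states).
#' @param traj Reference `ode_trajectory` covering the fit window.
#' @param times Evaluation times; default 512 uniform points over the window.
#' @return An [error_report()] over the state dimensions.
#' @export
state_error_report <- function(fit, traj, times = NULL) {
  if (is.null(times))
    times <- seq(fit$window[1], fit$window[2], length.out = 512L)
  pred <- predict(fit, times)
  truth <- make_observations(traj, times)$values
  error_report(pred, truth, names = colnames(truth))
}
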