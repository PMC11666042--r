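# Trainable parameter surrogates for inverse problems. Both kinds live in
# normalized parameter space so gradient balancing sees O(1) scales:
#  - "constant": a single trainable scalar (time-invariant parameter);
#  - "network": a small time-input MLP (time- or temperature-varying parameter).

#' Create a trainable parameter model
#'
#' @param kind `"constant"` or `"network"`.
#' @param net_spec Architecture for the network kind; default 4 hidden layers
#'   of 10 units (GELU).
#' @return Object of class `param_model`. Constant models start at a uniform
#'   draw in `(-0.5, 0.5)` of normalized space (so the denormalized start is
#'   random within the central half of the bounds, never pinned to the
#'   midpoint); network weights are Glorot-initialized.
#' @export
param_model <- function(kind = c("constant", "network"),
                        net_spec = network_spec(4L, 10L)) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    structure(list(kind = "constant", value = stats::runif(1L, -0.5, 0.5)),
              class = "param_model")
  } else {
    structure(list(kind = "network", net = mlp_init(net_spec, out_dim = 1L)),
              class = "param_model")
  }
}

pm_eval <- function(pm, tprime, keep_cache = FALSE) {
  n <- length(tprime)
  if (pm$kind == "constant") {
    list(U = matrix(pm$value, n, 1L), cache = NULL)
  } else {
    fw <- mlp_eval(pm$net, tprime, tangent = FALSE, keep_cache = keep_cache)
    list(U = fw$U, cache = fw$cache)
  }
}

# g: n x 1 adjoint of the (normalized) parameter output
pm_backward <- function(pm, cache, g) {
  if (pm$kind == "constant") sum(g)
  else mlp_backward(pm$net, cache, gU = g)
}

pm_nparams <- function(pm) if (pm$kind == "constant") 1L else net_nparams(pm$net)

pm_flatten <- function(pm_or_grad, pm = NULL) {
  if (is.numeric(pm_or_grad)) pm_or_grad
  else if (!is.null(pm_or_grad$kind) && pm_or_grad$kind == "constant")
    pm_or_grad$value
  else if (!is.null(pm_or_grad$kind)) net_flatten(pm_or_grad$net)
  else net_flatten(pm_or_grad)  # bare gradient list(W, b)
}

pm_unflatten <- function(pm, v) {
  if (pm$kind == "constant") { pm$value <- v[1L]; pm }
  else { pm$net <- net_unflatten(pm$net, v); pm }
}

#' Evaluate system parameters from trained models, in original units
#'
#' Known parameters come from their stored formulas; learnable parameters come
#' from their models, denormalized with the parameter bounds of `spec`.
#'
#' @param system An [ode_system()].
#' @param models Named list of [param_model()]s, one per learnable parameter.
#' @param times Query times in original units.
#' @param spec The [normalization_spec()] carrying the parameter bounds (and
#'   time window used to normalize the model input).
#' @return `n x P` matrix of parameter values in `param_spec` order.
#' @export
predict_params <- function(system, models, times, spec) {
  li <- learnable_params(system)
  vals <- list()
  if (length(li)) {
    tp <- normalize_time(times, spec)
    for (p in li) {
      nm <- system$param_spec[[p]]$name
      pm <- models[[nm]]
      if (is.null(pm)) stop("no model for learnable parameter '", nm, "'")
      vals[[nm]] <- denormalize_params(as.numeric(pm_eval(pm, tp)$U), spec, p)
    }
  }
  evaluate_params(system, times, models = vals)
}

#' Parameter bounds from the ground-truth formulas
#'
#' Min/max of each learnable parameter's true value over a dense grid of the
#' window, widened by a relative margin -- the bounds source for benchmark
#' inverse problems.
#'
#' @param system An [ode_system()].
#' @param window Length-2 time window.
#' @param margin Relative widening (default 0.1).
#' @param n Grid size.
#' @return List with `Ltheta`, `Utheta` (length `P`, `NA` for known entries).
#' @export
param_bounds_from_truth <- function(system, window, margin = 0.1, n = 512L) {
  tg <- seq(window[1], window[2], length.out = n)
  th <- evaluate_params(system, tg, use_truth = TRUE)
  P <- length(system$param_spec)
  Lt <- Ut <- rep(NA_real_, P)
  for (p in learnable_params(system)) {
    lo <- min(th[, p]); hi <- max(th[, p])
    pad <- margin * max(hi - lo, abs(hi), abs(lo), 1e-12)
    Lt[p] <- lo - pad; Ut[p] <- hi + pad
  }
  list(Ltheta = Lt, Utheta = Ut)
}

#' @export
print.param_model <- function(x, ...) {
  if (x$kind == "constant")
    cat("<param_model> constant, normalized value ", signif(x$value, 4), "\n",
        sep = "")
  else
    cat("<param_model> network (", net_nparams(x$net), " weights)\n", sep = "")
  invisible(x)
}
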