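# ODE system definitions: generic container, parameter specifications, and the
# built-in benchmark systems (Lorenz; 10-stage mosquito population dynamics;
# 1-D exponential decay used by the desk-scale benchmarks).

#' Parameter specification
#'
#' One entry of an ODE system's ordered parameter list.
#'
#' @param name Parameter label.
#' @param kind One of `"known_constant"`, `"known_function_of_time"`,
#'   `"learn_constant"`, `"learn_function_of_time"`. The `learn_*` kinds are
#'   exactly the entries the inverse machinery creates trainable models for.
#' @param value The true value: a number, or for function kinds a function
#'   `function(t, tau)` of time and (optionally) the forcing value. Used by the
#'   data generator and for error scoring only -- a `learn_*` parameter's value
#'   is never shown to the trainer.
#' @param bounds Optional `(L, U)` pair for normalization of a learnable
#'   parameter.
#' @export
param_spec <- function(name, kind = c("known_constant", "known_function_of_time",
                                      "learn_constant", "learn_function_of_time"),
                       value = NULL, bounds = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("known_function_of_time", "learn_function_of_time") &&
      !is.function(value))
    stop("parameter '", name, "': function kinds need a function value")
  if (kind %in% c("known_constant", "learn_constant") && !is.numeric(value))
    stop("parameter '", name, "': constant kinds need a numeric value")
  if (!is.null(bounds)) stopifnot(length(bounds) == 2L, bounds[1] <= bounds[2])
  structure(list(name = name, kind = kind, value = value, bounds = bounds),
            class = "param_spec")
}

#' Define an ODE system
#'
#' @param name System label.
#' @param state_dim State dimension `V` (also the number of equations here).
#' @param rhs Vectorized right-hand side `function(t, u, theta)` where `t` is a
#'   length-`n` vector, `u` an `n x V` matrix and `theta` an `n x P` matrix of
#'   parameter values already evaluated at each time; must return an `n x V`
#'   matrix of derivatives.
#' @param param_spec Ordered list of [param_spec()] entries.
#' @param state_names Length-`V` labels.
#' @param forcing Optional forcing function `function(t)` (e.g. temperature in
#'   degrees C) passed to time-dependent parameter formulas as `tau`.
#' @return Object of class `ode_system`.
#' @export
ode_system <- function(name, state_dim, rhs, param_spec = list(),
                       state_names = paste0("u", seq_len(state_dim)),
                       forcing = NULL) {
  stopifnot(state_dim >= 1L, is.function(rhs),
            length(state_names) == state_dim)
  structure(list(name = name, state_dim = as.integer(state_dim), rhs = rhs,
                 param_spec = param_spec, state_names = state_names,
                 forcing = forcing),
            class = "ode_system")
}

param_names <- function(system) {
  vapply(system$param_spec, `[[`, "", "name")
}

learnable_params <- function(system) {
  kinds <- vapply(system$param_spec, `[[`, "", "kind")
  which(startsWith(kinds, "learn"))
}

# safe rhs call with finiteness checks on the input state
eval_rhs <- function(system, t, u, theta) {
  if (!all(is.finite(u))) stop("non-finite state passed to rhs of '",
                               system$name, "'")
  out <- system$rhs(t, u, theta)
  if (!is.matrix(out) || ncol(out) != system$state_dim)
    stop("rhs of '", system$name, "' must return an n x V matrix")
  out
}

#' Evaluate the parameter vector of a system at given times
#'
#' Known constants are replicated, known functions are evaluated at `(t, tau)`
#' with `tau` the forcing value, and learnable entries are filled from the
#' supplied models (see [predict_params()]) or, with `use_truth = TRUE`, from
#' their true values -- the data-generation path.
#'
#' @param system An [ode_system()].
#' @param t Times (original units).
#' @param models Named list of trained parameter models for the `learn_*`
#'   entries (original-unit values are produced by the caller).
#' @param use_truth Evaluate `learn_*` entries from their stored true values.
#' @return `n x P` matrix of parameter values, columns in `param_spec` order.
#' @export
evaluate_params <- function(system, t, models = NULL, use_truth = FALSE) {
  n <- length(t)
  P <- length(system$param_spec)
  out <- matrix(NA_real_, n, P,
                dimnames = list(NULL, if (P) param_names(system)))
  if (P == 0L) return(out)
  tau <- if (!is.null(system$forcing)) system$forcing(t)
  for (p in seq_len(P)) {
    ps <- system$param_spec[[p]]
    known <- startsWith(ps$kind, "known")
    if (known || use_truth) {
      out[, p] <- if (is.function(ps$value)) ps$value(t, tau)
                  else rep(ps$value, n)
    } else {
      m <- models[[ps$name]]
      if (is.null(m))
        stop("no model bound for learnable parameter '", ps$name, "'")
      out[, p] <- m
    }
  }
  out
}

# ---- Lorenz -----------------------------------------------------------------

#' Lorenz system right-hand side
#'
#' `dx/dt = sigma (y - x)`, `dy/dt = x (rho - z) - y`, `dz/dt = x y - beta z`.
#' Vectorized over rows.
#'
#' @param t Times (unused; kept for the common rhs signature).
#' @param u `n x 3` state matrix, columns `(x, y, z)`.
#' @param theta `n x 3` parameter matrix, columns `(sigma, rho, beta)`.
#' @export
lorenz_rhs <- function(t, u, theta) {
  if (!all(is.finite(u))) stop("non-finite state passed to lorenz_rhs")
  x <- u[, 1L]; y <- u[, 2L]; z <- u[, 3L]
  cbind(theta[, 1L] * (y - x),
        x * (theta[, 2L] - z) - y,
        x * y - theta[, 3L] * z)
}

#' Ground-truth time-varying Lorenz parameters of the inverse benchmark
#'
#' `sigma(t) = (10/2) sin(2 pi t) + 10`, `rho(t) = (28/5) sin(2 pi t + pi/2) + 28`,
#' `beta = 8/3`; both sine terms have period 1.
#'
#' @param t Times.
#' @return `n x 3` matrix with columns `sigma`, `rho`, `beta`.
#' @export
lorenz_timevarying_params <- function(t) {
  cbind(sigma = 10 / 2 * sin(2 * pi * t) + 10,
        rho   = 28 / 5 * sin(2 * pi * t + pi / 2) + 28,
        beta  = rep(8 / 3, length(t)))
}

#' The Lorenz benchmark system
#'
#' With defaults this is the constant-parameter forward benchmark
#' (`sigma = 10, rho = 28, beta = 8/3`). `variant = "inverse"` switches to the
#' time-varying truth of [lorenz_timevarying_params()] with all three
#' parameters learnable (as small time-input networks).
#'
#' @param sigma,rho,beta Constant parameter values for the forward variant.
#' @param variant `"forward"` (known constants) or `"inverse"` (learnable,
#'   time-varying truth).
#' @export
lorenz_system <- function(sigma = 10, rho = 28, beta = 8 / 3,
                          variant = c("forward", "inverse")) {
  variant <- match.arg(variant)
  ps <- if (variant == "forward") {
    list(param_spec("sigma", "known_constant", sigma),
         param_spec("rho", "known_constant", rho),
         param_spec("beta", "known_constant", beta))
  } else {
    list(param_spec("sigma", "learn_function_of_time",
                    function(t, tau) lorenz_timevarying_params(t)[, "sigma"]),
         param_spec("rho", "learn_function_of_time",
                    function(t, tau) lorenz_timevarying_params(t)[, "rho"]),
         param_spec("beta", "learn_constant", 8 / 3))
  }
  ode_system("lorenz", 3L, lorenz_rhs, ps, state_names = c("x", "y", "z"))
}

# ---- mosquito population dynamics ------------------------------------------

#' Benchmark seasonal temperature forcing
#'
#' `tau(t) = 10 sin(2 pi t / 365) + 10` degrees C, `t` in days.
#'
#' @param t Time in days.
#' @export
sine_temperature <- function(t) 10 * sin(2 * pi * t / 365) + 10

#' Default mosquito rate registry (synthetic placeholders)
#'
#' Named list mapping each rate of the 10-stage model to a constant or a
#' temperature-response function `function(t, tau)`. The temperature responses
#' are synthetic placeholders with plausible Culex-like magnitudes (development
#' shuts down below a stage-specific threshold; mortality rises in the cold);
#' any registry entry can be overridden per experiment, and all case-study
#' behaviour is defined against whatever registry the configuration declares.
#'
#' Rates are per day; `kappa_L`, `kappa_P` are carrying capacities in
#' organisms; `beta1`, `beta2` are eggs laid per ovipositing adult per day;
#' `sigma_em` is the dimensionless emergence (sex-ratio) coefficient.
#'
#' @return Named list of constants and `function(t, tau)` entries.
#' @export
mosquito_default_rates <- function() {
  dev <- function(slope, thr) {
    force(slope); force(thr)
    function(t, tau) pmax(0, slope * (tau - thr))
  }
  cold_mort <- function(base, slope) {
    force(base); force(slope)
    function(t, tau) base + slope * pmax(0, 5 - tau)
  }
  list(
    gamma_Ao  = 2.0,     # oviposition -> bloodseeking transition (1/day)
    gamma_Aem = 1.5,     # emergence -> host seeking (1/day)
    gamma_Ab  = 0.2,     # bloodmeal -> gestation (1/day)
    beta1     = 141,     # eggs/day, nulliparous ovipositing adults
    beta2     = 80,      # eggs/day, parous ovipositing adults
    mu_E      = 0.1,     # egg mortality (1/day)
    mu_r      = 0.08,    # host-seeking risk mortality (1/day)
    mu_em     = 0.1,     # emergence mortality coefficient
    f_E       = dev(0.021, 3),   # egg development (1/day)
    f_L       = dev(0.0083, 4),  # larval development
    f_P       = dev(0.019, 4),   # pupal development
    f_Ag      = dev(0.012, 5),   # gonotrophic development
    m_L       = cold_mort(0.03, 0.01),  # larval mortality
    m_P       = cold_mort(0.025, 0.01), # pupal mortality
    m_A       = cold_mort(0.02, 0.005), # adult mortality
    kappa_L   = 1e8,     # larval carrying capacity (organisms)
    kappa_P   = 1e7,     # pupal carrying capacity (organisms)
    sigma_em  = 0.5      # emergence coefficient (dimensionless)
  )
}

mosquito_param_order <- c("gamma_Ao", "gamma_Aem", "gamma_Ab", "beta1", "beta2",
                          "mu_E", "mu_r", "mu_em", "f_E", "f_L", "f_P", "f_Ag",
                          "m_L", "m_P", "m_A", "kappa_L", "kappa_P", "sigma_em")

mosquito_stage_names <- c("E", "L", "P", "Aem", "Ab1", "Ag1", "Ao1",
                          "Ab2", "Ag2", "Ao2")

#' Mosquito stage-structured model right-hand side
#'
#' The 10 stage equations (egg, larva, pupa, emerging adults, and the
#' bloodseeking / gestating / ovipositing substages of nulliparous and parous
#' adults), with larval density dependence `m_L (1 + L / kappa_L)` and pupal
#' emergence factor `sigma_em exp(-mu_em (1 + P / kappa_P))`.
#'
#' @param t Times (unused directly; parameters are already evaluated).
#' @param u `n x 10` state matrix, columns in the order
#'   `E, L, P, Aem, Ab1, Ag1, Ao1, Ab2, Ag2, Ao2`.
#' @param theta `n x 18` parameter matrix in the order of
#'   `mosquito_default_rates()` (see [mosquito_system()]).
#' @param exponent_form Emergence exponent reading: `"P/kappaP"` (default,
#'   density-dependent) or `"1/kappaP"` (density-independent constant).
#' @export
mosquito_rhs <- function(t, u, theta, exponent_form = c("P/kappaP", "1/kappaP")) {
  exponent_form <- match.arg(exponent_form)
  if (!all(is.finite(u))) stop("non-finite state passed to mosquito_rhs")
  th <- function(nm) theta[, match(nm, mosquito_param_order)]
  if (any(th("kappa_L") <= 0) || any(th("kappa_P") <= 0))
    stop("carrying capacities kappa_L, kappa_P must be positive")
  E <- u[, 1L]; L <- u[, 2L]; P <- u[, 3L]; Aem <- u[, 4L]
  Ab1 <- u[, 5L]; Ag1 <- u[, 6L]; Ao1 <- u[, 7L]
  Ab2 <- u[, 8L]; Ag2 <- u[, 9L]; Ao2 <- u[, 10L]
  emer_exp <- if (exponent_form == "P/kappaP") {
    exp(-th("mu_em") * (1 + P / th("kappa_P")))
  } else {
    exp(-th("mu_em") * (1 + 1 / th("kappa_P")))
  }
  cbind(
    th("gamma_Ao") * (th("beta1") * Ao1 + th("beta2") * Ao2) -
      (th("mu_E") + th("f_E")) * E,
    th("f_E") * E - (th("m_L") * (1 + L / th("kappa_L")) + th("f_L")) * L,
    th("f_L") * L - (th("m_P") + th("f_P")) * P,
    th("f_P") * th("sigma_em") * emer_exp * P -
      (th("m_A") + th("gamma_Aem")) * Aem,
    th("gamma_Aem") * Aem - (th("m_A") + th("mu_r") + th("gamma_Ab")) * Ab1,
    th("gamma_Ab") * Ab1 - (th("m_A") + th("f_Ag")) * Ag1,
    th("f_Ag") * Ag1 - (th("m_A") + th("mu_r") + th("gamma_Ao")) * Ao1,
    th("gamma_Ao") * (Ao1 + Ao2) - (th("m_A") + th("mu_r") + th("gamma_Ab")) * Ab2,
    th("gamma_Ab") * Ab2 - (th("m_A") + th("f_Ag")) * Ag2,
    th("f_Ag") * Ag2 - (th("m_A") + th("mu_r") + th("gamma_Ao")) * Ao2
  )
}

#' The 10-stage mosquito population system
#'
#' @param rates Rate registry as from [mosquito_default_rates()]; individual
#'   entries may be overridden. Constants stay constants; functions are
#'   evaluated at the forcing temperature.
#' @param learn Character vector of rate names to mark learnable (the
#'   case-study inverse set is `gamma_Aem, gamma_Ab, gamma_Ao` as constants and
#'   `f_E, f_P, f_L, f_Ag, m_L, m_P, m_A` as time functions).
#' @param forcing Temperature forcing `function(t)`; default
#'   [sine_temperature()].
#' @param exponent_form Passed to [mosquito_rhs()].
#' @export
mosquito_system <- function(rates = mosquito_default_rates(),
                            learn = character(0),
                            forcing = sine_temperature,
                            exponent_form = c("P/kappaP", "1/kappaP")) {
  exponent_form <- match.arg(exponent_form)
  missing_r <- setdiff(mosquito_param_order, names(rates))
  if (length(missing_r)) stop("rate registry missing: ",
                              paste(missing_r, collapse = ", "))
  bad <- setdiff(learn, mosquito_param_order)
  if (length(bad)) stop("unknown learnable rates: ", paste(bad, collapse = ", "))
  if (rates$kappa_L <= 0 || rates$kappa_P <= 0)
    stop("carrying capacities must be positive")
  ps <- lapply(mosquito_param_order, function(nm) {
    v <- rates[[nm]]
    fn <- is.function(v)
    kind <- if (nm %in% learn) {
      if (fn) "learn_function_of_time" else "learn_constant"
    } else {
      if (fn) "known_function_of_time" else "known_constant"
    }
    param_spec(nm, kind, v)
  })
  names(ps) <- NULL
  ode_system("mosquito", 10L,
             function(t, u, theta) mosquito_rhs(t, u, theta, exponent_form),
             ps, state_names = mosquito_stage_names, forcing = forcing)
}

# ---- 1-D exponential decay (desk-scale benchmark) ---------------------------

#' Exponential decay benchmark system
#'
#' `du/dt = -theta u`, the 1-D system used by the desk-scale forward and
#' inverse benchmarks (closed form `u(t) = u0 exp(-theta t)`).
#'
#' @param rate True decay rate `theta`.
#' @param learn Mark the rate learnable (inverse benchmark).
#' @export
exponential_system <- function(rate = 1, learn = FALSE) {
  ode_system("exponential", 1L,
             function(t, u, theta) -theta[, 1L] * u,
             list(param_spec("theta",
                             if (learn) "learn_constant" else "known_constant",
                             rate)),
             state_names = "u")
}

#' Look up a built-in system by name
#'
#' @param name `"lorenz"`, `"mosquito"` or `"exponential"`.
#' @param ... Passed to the system constructor.
#' @export
get_system <- function(name, ...) {
  switch(name,
         lorenz = lorenz_system(...),
         mosquito = mosquito_system(...),
         exponential = exponential_system(...),
         stop("unknown system: ", name))
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system> ", x$name, ": V = ", x$state_dim, ", P = ",
      length(x$param_spec), sep = "")
  li <- learnable_params(x)
  if (length(li)) cat(" (", length(li), " learnable)", sep = "")
  cat("\n states:", paste(x$state_names, collapse = ", "), "\n")
  invisible(x)
}
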