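# MIN-MAX normalization of time, state and parameters, the bound-adjustment
# rule, and the residual rescale factors that turn the raw ODE residual into
# the normalized one the losses use.

#' Widen degenerate bounds
#'
#' When an upper/lower bound pair is narrower than 2 units, the bounds are
#' pushed out around their midpoint `M = (L + U) / 2` to `L' = min(L, M - 1)`,
#' `U' = max(U, M + 1)`, guaranteeing a normalization denominator of at least
#' 2 and keeping the normalized variable O(1). Wider bounds pass through
#' unchanged.
#'
#' @param L,U Numeric vectors of lower/upper bounds (recycled together).
#' @return List with components `L` and `U`.
#' @export
adjust_bounds <- function(L, U) {
  stopifnot(length(L) == length(U), all(L <= U))
  narrow <- (U - L) < 2
  if (any(narrow)) {
    M <- (L + U) / 2
    L[narrow] <- pmin(L, M - 1)[narrow]
    U[narrow] <- pmax(U, M + 1)[narrow]
  }
  list(L = L, U = U)
}

#' Normalization specification for a PINN problem
#'
#' Holds the time window and the per-dimension state (and per-parameter)
#' bounds defining the affine maps onto `[-1, 1]`. Bounds narrower than 2 are
#' widened by [adjust_bounds()] unless `adjust = FALSE`.
#'
#' @param window Length-2 numeric, the time window `(Tmin, Tmax)` in original
#'   units.
#' @param Lu,Uu State bounds, one entry per state dimension.
#' @param Ltheta,Utheta Optional parameter bounds (only needed for learnable
#'   parameters; entries for known parameters may be `NA`).
#' @param adjust Apply the bound-widening rule (default `TRUE`).
#' @return Object of class `normalization_spec`.
#' @export
normalization_spec <- function(window, Lu, Uu, Ltheta = NULL, Utheta = NULL,
                               adjust = TRUE) {
  stopifnot(length(window) == 2L, window[2] > window[1],
            length(Lu) == length(Uu), all(Lu <= Uu))
  if (adjust) {
    ab <- adjust_bounds(Lu, Uu); Lu <- ab$L; Uu <- ab$U
    if (!is.null(Ltheta)) {
      ok <- !is.na(Ltheta) & !is.na(Utheta)
      if (any(ok)) {
        ab <- adjust_bounds(Ltheta[ok], Utheta[ok])
        Ltheta[ok] <- ab$L; Utheta[ok] <- ab$U
      }
    }
  }
  structure(list(Tmin = window[1], Tmax = window[2], Lu = Lu, Uu = Uu,
                 Ltheta = Ltheta, Utheta = Utheta),
            class = "normalization_spec")
}

# identity maps: t' = t, u' = u. Used when normalization is ablated away so
# the same training code runs on original scales.
identity_norm_spec <- function(V, P = 0L) {
  normalization_spec(c(-1, 1), Lu = rep(-1, V), Uu = rep(1, V),
                     Ltheta = if (P > 0L) rep(-1, P),
                     Utheta = if (P > 0L) rep(1, P),
                     adjust = FALSE)
}

#' Time normalization onto `[-1, 1]` and its inverse
#'
#' `t' = 2 (t - Tmin) / (Tmax - Tmin) - 1`.
#'
#' @param t,tprime Times in original / normalized units.
#' @param spec A [normalization_spec()].
#' @export
normalize_time <- function(t, spec) {
  2 * (t - spec$Tmin) / (spec$Tmax - spec$Tmin) - 1
}

#' @rdname normalize_time
#' @export
denormalize_time <- function(tprime, spec) {
  (tprime + 1) * (spec$Tmax - spec$Tmin) / 2 + spec$Tmin
}

#' State normalization and its inverse
#'
#' Componentwise affine map `u' = 2 (u - Lu) / (Uu - Lu) - 1`. Values outside
#' the bounds map outside `[-1, 1]` without clipping, so a surrogate can
#' represent overshoot during training.
#'
#' @param u,uprime Numeric vector (one state) or matrix (rows = time points).
#' @param spec A [normalization_spec()].
#' @export
normalize_state <- function(u, spec) {
  aff_norm(u, spec$Lu, spec$Uu)
}

#' @rdname normalize_state
#' @export
denormalize_state <- function(uprime, spec) {
  aff_denorm(uprime, spec$Lu, spec$Uu)
}

#' Parameter normalization and its inverse
#'
#' Same affine map as [normalize_state()], using the parameter bounds.
#' `idx` selects which parameter columns the input corresponds to (useful when
#' only learnable parameters live in normalized space).
#'
#' @param theta,theta_prime Vector or matrix of parameter values.
#' @param spec A [normalization_spec()].
#' @param idx Integer indices into the parameter bounds (default: all).
#' @export
normalize_params <- function(theta, spec, idx = NULL) {
  i <- if (is.null(idx)) seq_along(spec$Ltheta) else idx
  aff_norm(theta, spec$Ltheta[i], spec$Utheta[i])
}

#' @rdname normalize_params
#' @export
denormalize_params <- function(theta_prime, spec, idx = NULL) {
  i <- if (is.null(idx)) seq_along(spec$Ltheta) else idx
  aff_denorm(theta_prime, spec$Ltheta[i], spec$Utheta[i])
}

aff_norm <- function(x, L, U) {
  if (is.matrix(x)) {
    n <- nrow(x)
    (x - rep(L, each = n)) / rep(U - L, each = n) * 2 - 1
  } else (x - L) / (U - L) * 2 - 1
}

aff_denorm <- function(x, L, U) {
  if (is.matrix(x)) {
    n <- nrow(x)
    (x + 1) * rep(U - L, each = n) / 2 + rep(L, each = n)
  } else (x + 1) * (U - L) / 2 + L
}

#' Residual rescale factor of one state dimension
#'
#' The factor `2 / (Uu_i - Lu_i)` multiplying the raw right-hand side inside
#' the normalized ODE residual (state chain rule). The full residual also
#' carries the time chain factor `(Tmax - Tmin) / 2`; see [ode_loss()].
#'
#' @param spec A [normalization_spec()].
#' @param i State dimension index (vectorized; default all).
#' @export
residual_scale <- function(spec, i = seq_along(spec$Lu)) {
  2 / (spec$Uu[i] - spec$Lu[i])
}

# combined multiplier applied to f(i): state chain times time chain
residual_factor <- function(spec) {
  residual_scale(spec) * (spec$Tmax - spec$Tmin) / 2
}

#' Derive state bounds from a trajectory
#'
#' Per-dimension min/max of the trajectory states over an optional time
#' window, widened by a relative margin. The usual bounds source for forward
#' benchmarks where ground truth is available.
#'
#' @param traj An `ode_trajectory`.
#' @param window Optional length-2 time window restricting the rows used.
#' @param margin Relative widening of the raw range (default 0).
#' @return List with `Lu`, `Uu`.
#' @export
bounds_from_trajectory <- function(traj, window = NULL, margin = 0) {
  st <- traj$states
  if (!is.null(window)) {
    keep <- traj$times >= window[1] & traj$times <= window[2]
    if (!any(keep)) stop("no trajectory samples inside the window")
    st <- st[keep, , drop = FALSE]
  }
  Lu <- apply(st, 2L, min); Uu <- apply(st, 2L, max)
  pad <- margin * pmax(Uu - Lu, abs(Uu), 1e-12)
  list(Lu = Lu - pad, Uu = Uu + pad)
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat("<normalization_spec> window [", x$Tmin, ", ", x$Tmax, "], ",
      length(x$Lu), " state dim(s)",
      if (!is.null(x$Ltheta)) paste0(", ", length(x$Ltheta), " parameter bound(s)"),
      "\n", sep = "")
  invisible(x)
}
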