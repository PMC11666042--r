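# Pointwise parameter identifiability: at each time, write the ODE system as a
# linear system in the unknown parameters (they enter every equation affinely
# given the state) and inspect the reduced row-echelon form of the coefficient
# matrix. A parameter whose column is free (non-pivot) can take arbitrary
# values at that time and is unidentifiable there.

#' Linearize the system in a subset of its parameters
#'
#' Writes `A theta_unknown = b` at one time point, where `b` is the state
#' derivative minus all known-parameter contributions. Coefficients are
#' extracted numerically by probing: the rhs is evaluated with each unknown
#' set to 1 (others 0) and the all-zero evaluation subtracted; a second probe
#' at 2 must double the contribution, which guards against non-affine
#' dependence.
#'
#' @param system An [ode_system()].
#' @param t Time point.
#' @param u State at `t` (length `V`).
#' @param dudt State derivative at `t` (length `V`).
#' @param unknown Character vector of parameter names treated as unknown; all
#'   remaining parameters are fixed at their true values.
#' @return List with `A` (`F x length(unknown)`) and `b` (length `F`).
#' @export
linearize_in_params <- function(system, t, u, dudt, unknown) {
  pn <- param_names(system)
  ui <- match(unknown, pn)
  if (anyNA(ui)) stop("unknown parameter name(s): ",
                      paste(unknown[is.na(ui)], collapse = ", "))
  theta0 <- evaluate_params(system, t, use_truth = TRUE)
  theta0[, ui] <- 0
  um <- matrix(u, 1L)
  f0 <- as.numeric(eval_rhs(system, t, um, theta0))
  A <- matrix(0, system$state_dim, length(ui),
              dimnames = list(system$state_names, unknown))
  for (j in seq_along(ui)) {
    th1 <- theta0; th1[, ui[j]] <- 1
    col1 <- as.numeric(eval_rhs(system, t, um, th1)) - f0
    th2 <- theta0; th2[, ui[j]] <- 2
    col2 <- as.numeric(eval_rhs(system, t, um, th2)) - f0
    if (max(abs(col2 - 2 * col1)) >
        1e-8 * max(1, max(abs(col1))))
      stop("rhs is not affine in parameter '", unknown[j],
           "' at the given state")
    A[, j] <- col1
  }
  list(A = A, b = dudt - f0)
}

#' Reduced row-echelon analysis of a coefficient matrix
#'
#' Entries are rounded to `precision_digits` decimal digits (matching the
#' numerical precision a trained surrogate can resolve) and the matrix is
#' reduced by Gauss--Jordan elimination with partial pivoting; values below
#' half a unit in the last rounded digit are treated as zero throughout the
#' elimination. Free (non-pivot) columns are the unidentifiable parameters.
#'
#' Rounding perturbs the matrix by up to half a unit in the last digit, so
#' pivot decisions are taken at the matching numerical-rank tolerance
#' `sqrt(m n) * 10^-precision * max(1, max|A|)` (with `10^-precision` in the
#' role of the machine unit): column `j` is a pivot when the numerical rank
#' (singular values above the tolerance) of the first `j` columns exceeds that
#' of the first `j - 1`. In exact arithmetic this is precisely the pivot set
#' of the classical reduced row-echelon form, and it stays consistent with the
#' SVD rank where plain elimination does not (pivot division can amplify the
#' rounding residue past any fixed threshold). The reduced matrix itself is
#' then formed by Gauss--Jordan restricted to the selected pivots.
#'
#' @param A Numeric matrix.
#' @param precision_digits Rounding precision (default 6).
#' @return List with `rank`, `pivot_cols`, `free_cols` and the reduced matrix
#'   `R`.
#' @export
rref_analysis <- function(A, precision_digits = 6L) {
  stopifnot(is.matrix(A), all(is.finite(A)))
  m <- nrow(A); n <- ncol(A)
  if (n == 0L || m == 0L)
    return(list(rank = 0L, pivot_cols = integer(0),
                free_cols = seq_len(n), R = A))
  R <- round(A, precision_digits)
  tol <- sqrt(m * n) * 10^(-precision_digits) * max(1, max(abs(R)))
  num_rank <- function(M) sum(svd(M, nu = 0, nv = 0)$d > tol)
  # leftmost pivots: columns at which the prefix numerical rank increases
  pivots <- integer(0)
  r_prev <- 0L
  for (col in seq_len(n)) {
    r_col <- num_rank(R[, seq_len(col), drop = FALSE])
    if (r_col > r_prev) {
      pivots <- c(pivots, col)
      r_prev <- r_col
      if (r_prev == m) break
    }
  }
  # Gauss--Jordan on the selected pivots for the canonical reduced form
  for (k in seq_along(pivots)) {
    col <- pivots[k]
    cand <- which.max(abs(R[k:m, col])) + k - 1L
    if (cand != k) R[c(k, cand), ] <- R[c(cand, k), ]
    R[k, ] <- R[k, ] / R[k, col]
    others <- setdiff(seq_len(m), k)
    R[others, ] <- R[others, ] - outer(R[others, col], R[k, ])
  }
  if (length(pivots) < m && length(pivots) > 0L)
    R[(length(pivots) + 1L):m, ][abs(R[(length(pivots) + 1L):m, ]) <= tol] <- 0
  list(rank = length(pivots), pivot_cols = pivots,
       free_cols = setdiff(seq_len(n), pivots), R = R)
}

#' Identifiability profile along a trajectory
#'
#' Runs the linearize-and-RREF analysis separately at each requested time,
#' taking states from the (noise-free) reference trajectory and derivatives
#' from the rhs evaluated on it. A parameter is flagged identifiable at a time
#' when its column is a pivot column.
#'
#' Before rounding, the coefficient matrix is equilibrated (each column, then
#' each row, scaled by its largest magnitude): equations and parameters carry
#' arbitrary units, and in the normalized coordinates a PINN actually works in
#' all entries are O(1), which is where a fixed decimal rounding precision is
#' meaningful. Pivot/free structure is invariant to such scalings in exact
#' arithmetic.
#'
#' @param system An [ode_system()].
#' @param traj Reference `ode_trajectory` covering `times`.
#' @param unknown Parameter names treated as unknown.
#' @param times Analysis times; default: the trajectory's own sample times.
#' @param precision_digits Rounding precision for [rref_analysis()].
#' @return An `identifiability_profile`: data.frame with `t`, `rank`, one
#'   logical column per unknown parameter (`TRUE` = identifiable at that
#'   time), and `n_free`.
#' @export
profile_over_time <- function(system, traj, unknown, times = NULL,
                              precision_digits = 6L) {
  if (is.null(times)) times <- traj$times
  states <- make_observations(traj, times)$values
  theta <- evaluate_params(system, times, use_truth = TRUE)
  dudt <- eval_rhs(system, times, states, theta)
  P <- length(unknown)
  flags <- matrix(NA, length(times), P, dimnames = list(NULL, unknown))
  rank <- integer(length(times))
  for (j in seq_along(times)) {
    lin <- linearize_in_params(system, times[j], states[j, ], dudt[j, ],
                               unknown)
    rr <- rref_analysis(equilibrate(lin$A), precision_digits)
    rank[j] <- rr$rank
    flags[j, ] <- seq_len(P) %in% rr$pivot_cols
  }
  out <- data.frame(t = times, rank = rank, flags,
                    n_free = P - rank, check.names = FALSE)
  class(out) <- c("identifiability_profile", "data.frame")
  out
}

# scale columns then rows by their largest magnitude (zeros left alone)
equilibrate <- function(A) {
  if (nrow(A) == 0L || ncol(A) == 0L) return(A)
  cs <- apply(abs(A), 2L, max); cs[cs == 0] <- 1
  A <- sweep(A, 2L, cs, "/")
  rs <- apply(abs(A), 1L, max); rs[rs == 0] <- 1
  sweep(A, 1L, rs, "/")
}
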