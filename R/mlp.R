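# Multilayer perceptron surrogates with a forward-mode tangent in the (single)
# time input and a reverse-mode gradient that differentiates through both the
# network value and its time derivative. All operations are batched over
# collocation/observation points (rows).

#' Network architecture specification
#'
#' Describes a fully-connected network mapping normalized time to one or more
#' normalized outputs. The solution surrogate defaults to 4 hidden layers of
#' 100 units; parameter surrogates default to 4 x 10.
#'
#' @param n_hidden Number of hidden layers.
#' @param width Units per hidden layer.
#' @param activation Hidden-layer activation, `"gelu"` (default, smooth) or
#'   `"tanh"`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_hidden = 4L, width = 100L, activation = c("gelu", "tanh")) {
  activation <- match.arg(activation)
  stopifnot(n_hidden >= 0L, width >= 1L)
  structure(list(n_hidden = as.integer(n_hidden), width = as.integer(width),
                 activation = activation),
            class = "network_spec")
}

# Activations are exact GELU x * Phi(x) (default) or tanh; their first two
# derivatives are needed because the ODE loss backpropagates through the
# network's time tangent. Both value and derivative statistics are computed
# inline in mlp_eval from a single pnorm/dnorm pair per layer and cached for
# the backward pass.

#' Initialize network weights (Glorot uniform)
#'
#' @param spec A [network_spec()].
#' @param out_dim Output dimension (state dimension for the solution network,
#'   1 for a parameter network).
#' @param in_dim Input dimension; 1 (normalized time) for all surrogates here.
#' @return An `mlp_net`: lists of weight matrices and bias vectors plus the
#'   activation name. Biases start at zero.
#' @export
mlp_init <- function(spec = network_spec(), out_dim = 1L, in_dim = 1L) {
  widths <- c(in_dim, rep(spec$width, spec$n_hidden), out_dim)
  L <- length(widths) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1L]
    a <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
    b[[l]] <- numeric(fan_out)
  }
  structure(list(W = W, b = b, activation = spec$activation, spec = spec),
            class = "mlp_net")
}

# forward pass over a batch of scalar inputs; optionally propagates the
# tangent d h / d t alongside and keeps per-layer caches for the backward pass
# (including the activation statistics, so the backward pass recomputes no
# pnorm/dnorm calls)
mlp_eval <- function(net, x, tangent = TRUE, keep_cache = FALSE) {
  n <- length(x)
  L <- length(net$W)
  gelu <- net$activation == "gelu"
  h <- matrix(x, n, 1L)
  d <- if (tangent) matrix(1, n, 1L) else NULL
  hs <- if (keep_cache) vector("list", L) else NULL
  ds <- zs <- dzs <- s1s <- auxs <- hs
  for (l in seq_len(L - 1L)) {
    if (keep_cache) { hs[[l]] <- h; ds[[l]] <- d }
    z <- h %*% net$W[[l]]
    z <- z + rep(net$b[[l]], each = n)
    if (tangent) dz <- d %*% net$W[[l]]
    if (gelu) {
      Phi <- pnorm(z); phi <- dnorm(z)
      h <- z * Phi
      s1 <- Phi + z * phi
      aux <- phi                 # sigma''(z) = phi * (2 - z^2)
    } else {
      tz <- tanh(z)
      h <- tz
      s1 <- 1 - tz * tz
      aux <- tz                  # sigma''(z) = -2 * tz * s1
    }
    if (tangent) d <- s1 * dz
    if (keep_cache) {
      zs[[l]] <- z; s1s[[l]] <- s1; auxs[[l]] <- aux
      if (tangent) dzs[[l]] <- dz
    }
  }
  if (keep_cache) { hs[[L]] <- h; ds[[L]] <- d }
  U <- h %*% net$W[[L]]
  U <- U + rep(net$b[[L]], each = n)
  dU <- if (tangent) d %*% net$W[[L]] else NULL
  list(U = U, dU = dU,
       cache = if (keep_cache) list(hs = hs, ds = ds, zs = zs, dzs = dzs,
                                    s1s = s1s, auxs = auxs,
                                    tangent = tangent) else NULL)
}

#' Evaluate a network at normalized times
#'
#' @param net An `mlp_net` from [mlp_init()].
#' @param tprime Vector of (normalized) input times.
#' @return Matrix of outputs, one row per input point.
#' @export
net_forward <- function(net, tprime) {
  mlp_eval(net, tprime, tangent = FALSE)$U
}

#' Exact derivative of the network output with respect to its time input
#'
#' Computed by forward-mode propagation of the input tangent through the
#' layers, so it is the derivative of the network function itself (no finite
#' differencing).
#'
#' @inheritParams net_forward
#' @return Matrix of derivatives `dU/dt'`, one row per input point.
#' @export
net_time_derivative <- function(net, tprime) {
  mlp_eval(net, tprime, tangent = TRUE)$dU
}

# Reverse pass. gU / gdU are the loss adjoints of the network output and of
# its input tangent; either may be NULL. Returns gradients shaped like the
# network (list W, list b). Handles the second-order term sigma''(z) * dz that
# the tangent path introduces.
mlp_backward <- function(net, cache, gU = NULL, gdU = NULL) {
  L <- length(net$W)
  gelu <- net$activation == "gelu"
  gW <- vector("list", L); gb <- vector("list", L)
  hs <- cache$hs; ds <- cache$ds
  n <- nrow(hs[[1L]])
  if (is.null(gU)) gU <- matrix(0, n, ncol(net$W[[L]]))
  has_t <- !is.null(gdU) && cache$tangent
  gW[[L]] <- crossprod(hs[[L]], gU)
  gb[[L]] <- colSums(gU)
  aH <- gU %*% t(net$W[[L]])
  aD <- NULL
  if (has_t) {
    gW[[L]] <- gW[[L]] + crossprod(ds[[L]], gdU)
    aD <- gdU %*% t(net$W[[L]])
  }
  for (l in rev(seq_len(L - 1L))) {
    s1 <- cache$s1s[[l]]
    if (has_t) {
      z <- cache$zs[[l]]; aux <- cache$auxs[[l]]
      s2 <- if (gelu) aux * (2 - z * z) else -2 * aux * s1
      aZ <- aH * s1 + aD * s2 * cache$dzs[[l]]
      aDZ <- aD * s1
      gW[[l]] <- crossprod(hs[[l]], aZ) + crossprod(ds[[l]], aDZ)
    } else {
      aZ <- aH * s1
      gW[[l]] <- crossprod(hs[[l]], aZ)
    }
    gb[[l]] <- colSums(aZ)
    if (l > 1L) {
      aH <- aZ %*% t(net$W[[l]])
      if (has_t) aD <- aDZ %*% t(net$W[[l]])
    }
  }
  list(W = gW, b = gb)
}

# flat-vector packing (layer order: W1, b1, W2, b2, ...)
net_nparams <- function(net) {
  sum(vapply(net$W, length, 1L)) + sum(vapply(net$b, length, 1L))
}

net_flatten <- function(g) {
  unlist(mapply(function(W, b) c(as.vector(W), b), g$W, g$b, SIMPLIFY = FALSE),
         use.names = FALSE)
}

net_unflatten <- function(net, v) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]][] <- v[pos + seq_len(nw)]; pos <- pos + nw
    nb <- length(net$b[[l]])
    net$b[[l]][] <- v[pos + seq_len(nb)]; pos <- pos + nb
  }
  net
}

#' @export
print.mlp_net <- function(x, ...) {
  widths <- vapply(x$W, ncol, 1L)
  cat("<mlp_net> ", nrow(x$W[[1L]]), " -> ",
      paste(widths, collapse = " -> "),
      " (", x$activation, ", ", net_nparams(x), " weights)\n", sep = "")
  invisible(x)
}
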