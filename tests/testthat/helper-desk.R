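# Shared desk-scale fixtures: the 1-D exponential-decay benchmark with a
# closed-form solution, built in code at test time.

desk_truth <- function(rate = 1, window = c(0, 2), n = 201L) {
  integrate_system(exponential_system(rate),
                   u0 = 1, eval_times = seq(window[1], window[2],
                                            length.out = n))
}

desk_spec <- function(truth = desk_truth(), window = c(0, 2)) {
  b <- bounds_from_trajectory(truth)
  normalization_spec(window, b$Lu, b$Uu)
}

# small solution network and short schedules keep unit-level training runs
# within seconds; the acceptance suite uses the full desk budgets
desk_config <- function(phases = c(200L, 800L, 500L), balance = TRUE,
                        nf = 64L, width = 32L, eval_every = 500L) {
  pinn_config(net = network_spec(2L, width),
              schedule = phase_schedule(phases[1], phases[2], phases[3],
                                        eval_every = eval_every),
              balancing = balancing_config(0.99, 100L, balance),
              nf = nf, eval_grid = 300L, log_every = 500L)
}

# fit a network to a target function by plain regression (Adam on MSE); used
# as a supervised oracle independent of the PINN loop
regress_net <- function(target_fun, tp, net_spec = network_spec(2L, 32L),
                        out_dim = 1L, steps = 3000L, lr = 1e-2, seed = 1L,
                        lr_final = NULL) {
  set.seed(seed)
  net <- mlp_init(net_spec, out_dim = out_dim)
  y <- matrix(target_fun(tp), ncol = out_dim)
  th <- net_flatten(net)
  opt <- adam_init(length(th))
  for (s in seq_len(steps)) {
    rate <- if (!is.null(lr_final) && s > steps / 2) lr_final else lr
    fw <- mlp_eval(net, tp, tangent = FALSE, keep_cache = TRUE)
    g <- mlp_backward(net, fw$cache, gU = 2 * (fw$U - y) / length(y))
    upd <- adam_step(opt, th, net_flatten(g), rate)
    th <- upd$theta; opt <- upd$state
    net <- net_unflatten(net, th)
  }
  net
}
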