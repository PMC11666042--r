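# odepinn

Physics-informed neural networks (PINNs) for systems of ordinary differential
equations, in R. The package is for modellers who have a mechanistic ODE —
an epidemiological compartment model, a stage-structured population model, a
chemical rate system — plus sparse observations, and who want a single
trainer that solves the forward problem (extrapolate the state from an
initial condition) and the inverse problem (recover unknown, possibly
time-varying rates from data) under the same loss.

A solution network `U(t)` (and, for inverse problems, parameter surrogates
`Θ(t)`) minimizes

```
L = L_data + (1/F) Σ_i λ_i L_f(i)
```

where `L_data` is the mean squared misfit against observations and `L_f(i)`
is the mean squared residual of equation `i` at randomly resampled
collocation times, both in min–max normalized coordinates. Four techniques
make this practical for stiff, multi-scale ODE systems:

* **ODE normalization** — time, state and parameters are affinely mapped to
  `[-1, 1]`, and the residual is rescaled consistently (state *and* time
  chain factors), so no variable or equation dominates by units alone.
* **Gradient balancing** — every `N` steps, each equation weight is steered
  toward `mean|∇W L_data| / max|∇W L_f(i)|` with exponential smoothing `α`,
  preventing stiff residuals from dragging training to the trivial "null
  solution" that ignores the data.
* **Causal training** — three phases: data fit only, then the full loss with
  a collocation interval growing forward in time (respecting causality),
  then full-window tuning with early stopping on a λ=1 evaluation loss.
* **Domain decomposition** — long windows are split into equal cores trained
  sequentially on overlap-extended subdomains; each subdomain's predictions
  on the overlap become the next one's data condition, and the stitched
  predictor answers each query from the core that owns it.

Included besides the trainer: a high-accuracy reference integrator
(deSolve, Dormand–Prince 4(5), tolerances 1e-9) that generates all synthetic
ground truth; the Lorenz benchmark system and a 10-stage temperature-forced
mosquito population model (egg → larva → pupa → emerging adults → the
bloodseeking/gestating/ovipositing substages of nulliparous and parous
females) with a configurable temperature-rate registry; the RMSE/MAE/MDAPE/
nRMSE error reports; and a pointwise parameter-identifiability analysis that
linearizes the system in its unknown rates and inspects the reduced
row-echelon form of the coefficient matrix at each time.

## Worked example: recovering a decay rate

Recover the constant rate `θ = 0.5` of `du/dt = −θ u` from 21 noiseless
observations on `[0, 2]`, training the solution network and the parameter
scalar jointly:

```r
library(odepinn)

sys   <- exponential_system(rate = 0.5, learn = TRUE)
truth <- integrate_system(sys, u0 = 1, eval_times = seq(0, 2, length.out = 201))
obs   <- make_observations(truth, seq(0, 2, length.out = 21))

cfg <- pinn_config(net = network_spec(2, 32),
                   schedule = phase_schedule(500, 4000, 2000, eval_every = 1000),
                   nf = 64, eval_grid = 300)
fit <- recover_parameters(sys, obs, window = c(0, 2), config = cfg, seed = 1)
fit
#> <pinn_fit> exponential on [0, 2], stopped at step 6500
#>   best evaluation loss 1.843e-06 (step 6500)

round(predict(fit, c(0, 1, 2), what = "params"), 4)
#>       theta
#> [1,] 0.4997
#> [2,] 0.4997
#> [3,] 0.4997

param_error_report(fit)
#>   dimension         RMSE          MAE        MDAPE        nRMSE
#> 1     theta 0.0002577638 0.0002577638 0.0005155276 0.0005155276
#> 2   Overall 0.0002577638 0.0002577638 0.0005155276 0.0005155276
```

The evaluation loss is the combined loss with all equation weights at 1 on a
fixed dense grid — the quantity early stopping monitors. The recovered rate
is constant over time (a single trainable scalar in normalized parameter
space) and lands within 0.06% of the truth; MDAPE is reported as a fraction,
and for a constant truth the nRMSE normalizer falls back from the (zero)
range to the mean absolute truth, as recorded in the report.

Forward problems use the same entry point with known parameters
(`pinn_train()`), long windows go through `partition()` +
`train_decomposed()`, benchmark experiment presets through
`experiment_config()` / `run_experiment()`, and
`profile_over_time()` maps when each unknown rate of a system is structurally
identifiable along a trajectory. `vignettes/odepinn-methods.Rmd` documents
the method, every tunable parameter, and the package's numerical choices. A
thin command-line front end lives at `inst/cli/odepinn.R`
(`simulate` / `train` / `invert` / `decompose` / `identify` / `report`).

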