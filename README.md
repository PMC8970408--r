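# predcoding

Predictive coding and backpropagation for feedforward neural networks, in R.

## The scientific problem

Backpropagation is the workhorse for training artificial neural networks,
but its credit assignment is biologically awkward: the update to a weight in
one layer depends on activity in all deeper layers. Predictive coding is a
theory of cortical processing in which each layer carries *beliefs* about
latent causes and exchanges only local *prediction errors* with its
neighbors, and it has been proposed as a biologically plausible route to
gradient learning. This package implements, from first principles, the
algorithms needed to study the mathematical relationship between the two for
supervised learning in layered networks — for computational neuroscientists
and machine-learning researchers who want to verify, probe, or extend that
relationship numerically.

## The model

A feedforward network is a chain
`vhat_0 = x`, `vhat_l = f_l(vhat_{l-1}; theta_l)`, `l = 1..L`, with loss
`L(yhat, y)` at the output `yhat = vhat_L`. Three update rules share one
interface:

* **Backpropagation** (`err_type = "exact"`): the reference recursion
  `delta_L = dL/dvhat_L`, `delta_l = delta_{l+1} df_{l+1}/dvhat_l`,
  `dtheta_l = -delta_l df_l/dtheta_l`, built on per-layer row-form
  vector-Jacobian products (no Jacobian is ever materialized).
* **Strict predictive coding** (`"strict"`): beliefs `v_l` (initialized at
  `vhat_l`) descend the free energy
  `F = 1/2 sum_l ||eps_l||^2`, `eps_l = f_l(v_{l-1}) - v_l`, by
  `v_l <- v_l + eta * (eps_l - eps_{l+1} df_{l+1}(v_l)/dv_l)` for `n`
  iterations; then `dtheta_l = -eps_l df_l(v_{l-1})/dtheta_l`. Its converged
  updates are *not* the true gradients, yet still support learning.
* **Fixed-prediction predictive coding** (`"fixed_pred"`): predictions and
  linearization points are frozen at the forward-pass activations
  (`eps_l = vhat_l - v_l`). Converged updates equal backpropagation's, and
  with step size `eta = 1` the equivalence is exact after `n = L`
  iterations: the error at layer `l` is touched exactly once, on iteration
  `i = L - l + 1`, when it becomes `delta_l`.

Precision-weighted errors `eps~_l = eps_l P_l` (with `P_l` the inverse
covariance of layer `l`'s Gaussian model) are supported: hidden-layer
precisions alter the inference trajectory but not the converged updates,
while an output precision `P_L` (squared-Euclidean loss only) rescales the
converged updates by `P_L`.

Supporting machinery: a central finite-difference gradient oracle,
fixed-point residual diagnostics, relative-error/angle comparison sweeps, a
seeded mini-batch training loop (SGD and Adam driven by any algorithm's
`dtheta`), synthetic dataset generators (Gaussian blobs, teacher networks,
image-shaped textures), JSON model/checkpoint serialization, and a CLI.

## Worked example

```r
library(predcoding)

model <- with_seed(1, network(list(
  layer_block(list(layer_affine(8, 16), layer_tanh(16))),
  layer_affine(16, 4))))
data <- make_blobs(seed = 2, n_samples = 240, dim = 8, K = 4)
test <- make_blobs(seed = 3, n_samples = 120, dim = 8, K = 4,
                   centers = data$descriptor$centers)
loss <- loss_squared_euclidean()

bp <- backprop_update(model, loss, data$x[1:32, ], data$y[1:32, ])
fp <- pc_infer(model, loss, data$x[1:32, ], data$y[1:32, ],
               err_type = "fixed_pred", eta = 1, n = 2)
st <- pc_infer(model, loss, data$x[1:32, ], data$y[1:32, ],
               err_type = "strict", eta = 0.05, tol = 1e-8)
```

This prints (package version 0.1.0):

```
mini-batch loss: 0.7331
max relative error, fixed_pred (eta=1, n=L) vs backprop: 1.63e-15
strict PC: 276 inference iterations; per-layer relative error vs backprop: 0.0115 0.0145
```

With `eta = 1` and `n = L = 2` the fixed-prediction algorithm reproduces the
backpropagation updates to machine precision (the exact-equivalence
theorem), while strict predictive coding converges to a *different* fixed
point — its updates deviate by 1-2% here — and nevertheless trains the
network:

```r
cfg <- train_config(err_type = "strict", eta = 0.1, n = 20, optimizer = "adam",
                    learning_rate = 5e-3, batch_size = 32, epochs = 25,
                    seed = 42, eval_every = 50)
fit <- train(model, data, cfg, test_data = test)
tail(fit$metrics, 2)
#  step   train_loss train_accuracy    test_loss test_accuracy
#   150 0.0005413902              1 0.0003561812             1
#   200 0.0003623223              1 0.0002456959             1
```

## Command line

```sh
inst/cli/predcoding train     --config cfg.json --out out/
inst/cli/predcoding compare   --config cfg.json --out out/   # (eta, n) sweep vs backprop
inst/cli/predcoding gradcheck --config cfg.json --out out/
inst/cli/predcoding make-data --config cfg.json --out out/
```

See `?pc_main` for the config schema; `--seed`, `--err-type`, `--eta`, `--n`
override config fields.

## Further reading

The methods vignette (`vignettes/predictive-coding.Rmd`) documents the
algorithms, sign and batch-reduction conventions, numerical choices, what
the synthetic generators do and do not emulate, and known limitations.
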