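---
title: "Predictive coding as a learning algorithm: models, conventions, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive coding as a learning algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predcoding)
```

## The model and its assumptions

A feedforward network is a chain of differentiable stages
$\hat v_0 = x$, $\hat v_\ell = f_\ell(\hat v_{\ell-1}; \theta_\ell)$ for
$\ell = 1, \dots, L$, trained to minimize a loss
$\mathcal{L}(\hat y, y)$ at the output $\hat y = \hat v_L$. Predictive
coding re-derives learning in this chain from a hierarchical Gaussian
model: each layer carries a *belief* $v_\ell$ about its latent state, the
layer above *predicts* it as $f_\ell(v_{\ell-1};\theta_\ell)$, and the
mismatch is the *prediction error*
$\epsilon_\ell = f_\ell(v_{\ell-1};\theta_\ell) - v_\ell$. Inference is
gradient descent of the free energy
$F = \tfrac12\sum_\ell \|\epsilon_\ell\|^2$ on the beliefs; learning is
gradient descent of $F$ on the parameters. All errors are row-form
adjoints, and every Jacobian contraction is a vector-Jacobian product —
full Jacobians are never formed. Mini-batches are handled as $m \times
n_\ell$ matrices (or $m \times C \times H \times W$ arrays for image
layers).

The package implements three update rules behind one interface
(`pc_infer()`):

1. **Backpropagation** (`"exact"`): the standard backward recursion;
   `eps` holds $\delta_\ell = \partial\mathcal{L}/\partial\hat v_\ell$.
2. **Strict predictive coding** (`"strict"`): beliefs start at the
   forward-pass activations and follow
   $v_\ell \leftarrow v_\ell + \eta\, dv_\ell$ with
   $dv_\ell = \epsilon_\ell - \epsilon_{\ell+1}\,
   \partial f_{\ell+1}(v_\ell)/\partial v_\ell$, the output error being
   recomputed each iteration from $\tilde v_L = f_L(v_{L-1})$. At a fixed
   point the errors satisfy
   $\epsilon_\ell^* = \epsilon_{\ell+1}^* \partial f_{\ell+1}(v^*_\ell)/\partial v^*_\ell$,
   which is *not* the chain rule at the forward activations, so the
   converged updates generally differ from the true gradients.
3. **Fixed-prediction predictive coding** (`"fixed_pred"`): predictions
   and linearization points are frozen at $\hat v_\ell$ and
   $\epsilon_\ell = \hat v_\ell - v_\ell$; the output error is computed
   once from the forward pass and held fixed. The fixed points now *are*
   the backpropagation gradients, and with $\eta = 1$ the iteration
   reaches them exactly: $\epsilon_\ell$ is changed exactly once, on
   iteration $i = L - \ell + 1$, so all layers are exact at $n = L$.
   With $\eta = 1$ the inference loop visits no other nonzero values —
   the algorithm is backpropagation with extra zero-valued steps, which
   is why the package treats backpropagation as the natural reference
   oracle for it.

## Conventions that matter

**Sign of the errors.** The source literature mixes two conventions
($\epsilon_\ell = f_\ell(\cdot) - v_\ell$ versus its negative, which flips
signs in the belief update but leaves $F$ unchanged). We adopt the
self-consistent gradient-descent set: strict predictive coding uses
$\epsilon_\ell = f_\ell(v_{\ell-1}) - v_\ell$ together with
$dv_\ell = \epsilon_\ell - \epsilon_{\ell+1} J_{\ell+1}$ (verified
numerically as $dv = -\partial F/\partial v$, see the property tests), and
the fixed-prediction variant uses $\epsilon_\ell = \hat v_\ell - v_\ell$
with the same $dv$ form, which reproduces the exact-equivalence induction
with the stated positive sign.

**Loop order and stale errors.** The inner sweep runs
$\ell = L-1, \dots, 1$, computing $\epsilon_\ell$, then $dv_\ell$, then
updating $v_\ell$ — the exact pseudocode order, on which the
$\eta = 1$ induction depends ($\epsilon_{\ell+1}$ must be updated before
$\epsilon_\ell$ within an iteration). Parameter updates use the error
values left by the final sweep. For strict predictive coding,
`refresh_errors = TRUE` optionally recomputes the errors from the final
beliefs first; both behaviors are exposed because the literature does not
state which was used during training. For the fixed-prediction variant the
final sweep's errors are used unconditionally: recomputing them from the
final beliefs would shift the $\eta = 1$ completion schedule one iteration
early (layer $\ell$ correct at $i = L - \ell$ instead of $L - \ell + 1$)
and break the defining property that completion happens exactly at
$n = L$.

**Batch reduction.** Losses are means over the batch and the factor
$1/m$ lives in the output gradient returned by `loss_and_output_grad()`;
the parameter adjoints `layer_vjp_params()` *sum* over the batch. The
composition makes `dtheta` equal $-\partial(\text{mean loss})/\partial\theta$
and hence batch-size invariant in magnitude, and is what the central
finite-difference oracle checks. Hidden-layer prediction errors remain
per-sample arrays without the $1/m$ (they are primal quantities, not loss
adjoints). A consequence worth knowing: for $m > 1$ the strict free energy
mixes the two scales, so the per-iteration descent monitor recorded in
`diagnostics$free_energy` is
$\tfrac12\sum_{\ell<L}\|\epsilon_\ell\|_F^2 + \mathcal{L}(\tilde v_L, y)$ —
exactly the objective whose negative belief-gradient is the implemented
$dv$ for any batch size and any loss — while the exported `free_energy()`
keeps the textbook form $\tfrac12\sum_\ell\|\epsilon_\ell\|^2$; the two
coincide at $m = 1$.

**Non-Euclidean losses.** For the squared-Euclidean loss the strict output
error $\epsilon_L = \partial\mathcal{L}(\tilde v_L, y)/\partial\tilde v_L$
equals $f_L(v_{L-1}) - y$ and the free-energy picture is exact. For
softmax cross-entropy the same definition is used and recomputed every
iteration, but the belief dynamics keep the first-order $dv$ (second-order
loss terms are dropped); this is a documented heuristic — the fixed-point
updates have no clean gradient interpretation in that case. The
fixed-prediction variant is exact for arbitrary losses.

**Precision weighting.** With hidden precisions $P_\ell$ the errors become
$\tilde\epsilon_\ell = (\hat v_\ell - v_\ell) P_\ell$ (row convention).
The fixed-point equations are unchanged, so hidden precisions change the
inference trajectory but not the converged updates — "accounting for
covariances does not affect learning" — which the tests verify to 1e-3
against backpropagation. An output precision is only meaningful under a
Gaussian output model, hence it is restricted to the squared-Euclidean
loss, where it rescales the converged updates by $P_L$ (verified exactly
for $P_L = cI$ via the $\eta = 1$ schedule). Diagonal precisions are
vectors, full precisions must be symmetric positive definite (checked by
eigendecomposition at construction). Learning the precisions themselves is
out of scope.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `eta` | inference step size (unitless) | 0.1 | `1` gives exact gradients for `fixed_pred` at `n = L`; large values make strict PC diverge (guarded, error class `pc_divergence_error`, bound 1e8) |
| `n` | inference iterations | 20 | mirrors common practice (20-200 in the literature); `tol` switches to a `max ||dv||_inf < tol` stopping rule capped at `max_iter = 10000` |
| `h` | finite-difference step | 1e-5 | central differences; exact for quadratics, otherwise O(h^2) truncation |
| `max_params` | oracle cap | 2000 | the oracle costs 2 forward passes per scalar parameter |
| optimizer | SGD or Adam | Adam(1e-3) | Adam uses standard bias-corrected moments (0.9, 0.999, 1e-8); the algorithm's `dtheta` is fed as `-gradient` |

Parameter initialization is fan-in-scaled uniform
($\pm 1/\sqrt{\text{fan-in}}$) under an explicit seed; every stochastic
component of the package (initialization, data generation, mini-batch
shuffling) flows from explicit seeds and restores the caller's RNG state.

## The synthetic data generators

The generators stand in for the image benchmarks used in the source
experiments, which require downloads and large models; nothing in the test
suite touches the network. `make_blobs()` produces $K$ well-separated
Gaussian clusters (default separation 6 at unit noise, giving Bayes
accuracy > 0.99 in 10 dimensions) — linearly separable structure on which
any of the three algorithms should reach high accuracy quickly.
`make_teacher_dataset()` labels random inputs by a frozen random network,
guaranteeing realizable structure; `make_image_batches()` provides
class-conditional smoothed textures in $[0,1]$ with image shape for
exercising convolutional layers. All are pure functions of their
descriptors (bit-identical regeneration), and held-out splits reuse the
training class structure (e.g. blob centers) with fresh noise under a
disjoint seed.

What a green test on these establishes: algorithmic correctness
(equivalence theorems, fixed-point equations, oracle agreement) and
qualitative trainability. What it does not establish: behavior at
real-data scale — feature correlations, class overlap, depth > 6,
parameter counts beyond a few thousand, or wall-clock competitiveness.

## Numerical choices

* ReLU subgradient at 0 is 0; finite-difference comparisons avoid kink
  points by construction.
* Convolution is stride-1, zero-padding-free, implemented by im2col and a
  single matrix product — correctness over speed at test scales.
* Cosine similarities are clipped to $[-1, 1]$ before `acos`, and the
  angle between bit-identical vectors is defined as exactly 0 to avoid
  `acos` round-off at the boundary.
* `relative_error()` refuses a zero reference; `update_angle()` refuses
  zero vectors. Sweeps record a zero-valued (not-yet-updated) layer's
  angle as `NA` and divergent runs as flagged rows rather than errors.
* Comparison norms are per layer on flattened parameter vectors, with a
  whole-model aggregate reported as layer 0.
* Argmax ties in accuracy evaluation break to the lowest class index.

## Design choices where the design was open

* **Labels are 1-based** everywhere (R convention); `one_hot(2, 4)` is
  `[0, 1, 0, 0]`.
* **`v[[L]]` convention:** strict predictive coding returns the final
  prediction $\tilde v_L = f_L(v_{L-1})$ in the last belief slot; the
  fixed-prediction variant returns $\hat v_L - \epsilon_L$, the value the
  output belief would take at the fixed point.
* **Checkpoints and model descriptions are JSON** (full-precision doubles,
  one named array per parameter): plain text, diffable, no binary formats.
* **The training loop re-evaluates metrics on the full train/test sets**
  at logging steps rather than on the current mini-batch, trading a little
  compute for comparable curves across algorithms.

## Known limitations

* Strictly a chain of layers: no recurrence, no general graphs, no
  pooling or normalization layers (blocks can compose the provided kinds).
* The strict fixed point is assumed unique when diagnostics interpret it;
  for strongly non-convex belief landscapes (large $\eta$, deep relu
  networks) the iteration can diverge — detected, not repaired.
* Precision weighting applies to vector-shaped (2-d) activations.
* One caveat established empirically by this package's diagnostics: at
  *full convergence* the strict algorithm's deviation from
  backpropagation is of the same order at every layer (it scales like
  $\|J\|^2/m$, not with the loss), with the output layer slightly worse
  because its update also moves its linearization point. The familiar
  "early layers differ, deep layers agree" picture describes *partially
  converged* inference, where deep-layer errors converge first; the
  package reproduces that regime at finite $n$ in the test suite.
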