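#' Per-layer precision matrices for precision-weighted prediction errors
#'
#' In the hierarchical Gaussian view, each hidden layer l has a covariance
#' Sigma_l whose inverse P_l (the precision) re-weights the prediction error
#' as `eps_tilde_l = eps_l %*% P_l` (row convention).  Hidden precisions
#' change the inference trajectory but not the converged parameter updates;
#' an output precision (squared-Euclidean loss only) rescales the converged
#' updates by `P_L`.
#'
#' @param hidden List with one entry per hidden layer `l = 1..L-1`: `NULL`
#'   (identity), a positive vector (diagonal), or a symmetric positive
#'   definite matrix.
#' @param output Optional output precision: a positive scalar `c` (meaning
#'   `c * I`), positive vector, or symmetric positive definite matrix.  Only
#'   valid with the squared-Euclidean loss.
#' @return A `pc_precision` object.
#' @export
precision_spec <- function(hidden = list(), output = NULL) {
  validate_prec <- function(P, where) {
    if (is.null(P)) return(invisible(NULL))
    if (is.matrix(P)) {
      if (!isTRUE(all.equal(P, t(P), tolerance = 1e-10))) {
        pc_stop("pc_precision_error", "%s precision matrix is not symmetric", where)
      }
      ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) {
        pc_stop("pc_precision_error", "%s precision matrix is not positive definite", where)
      }
    } else if (any(P <= 0)) {
      pc_stop("pc_precision_error", "%s diagonal precision has non-positive entries", where)
    }
    invisible(NULL)
  }
  for (l in seq_along(hidden)) validate_prec(hidden[[l]], sprintf("hidden layer %d", l))
  validate_prec(output, "output")
  structure(list(hidden = hidden, output = output), class = "pc_precision")
}

# eps %*% P for identity/diagonal/full precisions; eps is (m, n)
apply_precision <- function(eps, P) {
  if (is.null(P)) return(eps)
  if (length(dim(eps)) != 2L) {
    pc_stop("pc_precision_error", "precision weighting requires 2-d (vector-layer) activations")
  }
  if (is.matrix(P)) eps %*% P
  else if (length(P) == 1L) eps * P
  else {
    stopifnot(length(P) == ncol(eps))
    eps * rep(P, each = nrow(eps))
  }
}

hidden_precision <- function(precision, l) {
  if (is.null(precision)) return(NULL)
  if (l <= length(precision$hidden)) precision$hidden[[l]] else NULL
}

#' Free energy of a set of prediction errors
#'
#' The total summed magnitude of (possibly precision-weighted) prediction
#' errors, `F = (1/2) * sum_l ||eps_l||^2` (Frobenius norms across the
#' batch).  Pass precision-weighted errors to obtain the precision-weighted
#' free energy.
#'
#' @param eps List of prediction-error arrays.
#' @param batch_mean If `TRUE`, divide by the batch size for a mean-reduced
#'   value (identical at m = 1).
#' @return Scalar.
#' @export
free_energy <- function(eps, batch_mean = FALSE) {
  f <- sum(vapply(eps, function(e) sum(e^2), 0)) / 2
  if (batch_mean) f <- f / batch_size(eps[[1L]])
  f
}

# descent monitor for the strict belief dynamics: the objective whose
# negative v-gradient is the implemented dv for any batch size and any loss
strict_objective <- function(model, loss, x, y, v) {
  L <- model$L
  total <- 0
  v_prev <- x
  for (l in seq_len(L - 1L)) {
    e <- layer_forward(model$layers[[l]], v_prev) - v[[l]]
    total <- total + sum(e^2) / 2
    v_prev <- v[[l]]
  }
  vtl <- layer_forward(model$layers[[L]], v[[L - 1L]])
  total + loss_and_output_grad(loss, vtl, y)$value
}

check_divergence <- function(v, bound, iter) {
  for (l in seq_along(v)) {
    if (is.null(v[[l]])) next
    if (!all(is.finite(v[[l]])) || max(abs(v[[l]])) > bound) {
      pc_stop("pc_divergence_error",
              "belief dynamics diverged at layer %d, iteration %d", l, iter)
    }
  }
  invisible(NULL)
}

new_pc_result <- function(vhat, loss_value, dLdy, v, eps, dtheta, diagnostics,
                          err_type, iters) {
  structure(list(vhat = vhat, loss = loss_value, dLdy = dLdy, v = v, eps = eps,
                 dtheta = dtheta, diagnostics = diagnostics,
                 err_type = err_type, iters = iters),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("<pc_result: err_type=%s, loss=%.6g, %d inference iterations>\n",
              x$err_type, x$loss, x$iters))
  invisible(x)
}

#' One predictive-coding or backpropagation step
#'
#' Computes prediction errors, beliefs, and parameter updates for one
#' mini-batch under one of three algorithms selected by `err_type`:
#'
#' * `"exact"`: plain backpropagation; `eps` holds the activation gradients
#'   `delta_l = dL/dvhat_l` and `dtheta_l = -delta_l . df_l/dtheta_l`.
#' * `"strict"`: the unmodified free-energy scheme.  Beliefs `v_l` start at
#'   the forward-pass activations and descend
#'   `F = (1/2) sum_{l<L} ||f_l(v_{l-1}) - v_l||^2 + L(f_L(v_{L-1}), y)`
#'   for `n` iterations of `v_l <- v_l + eta * dv_l` with
#'   `dv_l = eps_l - eps_{l+1} . df_{l+1}(v_l)/dv_l`,
#'   `eps_l = f_l(v_{l-1}) - v_l`, and the output error recomputed each
#'   iteration from `vtilde_L = f_L(v_{L-1})`.  Its converged updates are
#'   generally not the true gradients.
#' * `"fixed_pred"`: the fixed prediction assumption.  Predictions and
#'   Jacobian linearization points are frozen at the forward-pass
#'   activations, `eps_l = vhat_l - v_l`, and the output error
#'   `eps_L = dL/dvhat_L` is held fixed.  With `eta = 1` and `n = L` the
#'   returned `eps` and `dtheta` equal backpropagation's exactly.
#'
#' Parameter updates are returned in the negative-gradient sense: a gradient
#' optimizer should treat `-dtheta` as its gradient.
#'
#' @param model A `pc_network`.
#' @param loss A `pc_loss`.
#' @param x Input batch.
#' @param y Targets (see [loss_and_output_grad()]).
#' @param err_type One of `"exact"`, `"strict"`, `"fixed_pred"`.
#' @param eta Inference step size (ignored for `"exact"`).
#' @param n Number of inference iterations (ignored for `"exact"`).
#' @param v_init Optional list of initial beliefs for hidden layers
#'   `1..L-1`; defaults to the forward-pass activations.
#' @param precision Optional [precision_spec()].  Hidden precisions apply to
#'   `"strict"` and `"fixed_pred"`; an output precision requires the
#'   squared-Euclidean loss.
#' @param refresh_errors For `"strict"`: recompute the errors from the final
#'   beliefs before the parameter update instead of using the values left by
#'   the last inference sweep (the pseudocode-literal default).  Ignored for
#'   `"fixed_pred"`, which always uses the final sweep's errors as in the
#'   pseudocode.
#' @param tol Optional convergence threshold: stop when
#'   `max_l ||dv_l||_inf < tol` (capped at `max_iter` iterations; overrides
#'   `n`).
#' @param max_iter Iteration cap when `tol` is given.
#' @param divergence_bound Abort with a divergence error when any belief
#'   magnitude exceeds this bound.
#' @return A `pc_result` with fields `vhat` (forward activations, including
#'   the input as element 1), `loss`, `dLdy`, `v` (beliefs), `eps`
#'   (per-layer errors), `dtheta` (per-layer named update arrays),
#'   `diagnostics` (per-iteration data frame), `iters`.
#' @references Whittington & Bogacz (2017) Neural Computation 29(5);
#'   Millidge, Tschantz & Buckley (2020) arXiv:2006.04182.
#' @export
pc_infer <- function(model, loss, x, y,
                     err_type = c("exact", "strict", "fixed_pred"),
                     eta = 0.1, n = 20L, v_init = NULL, precision = NULL,
                     refresh_errors = FALSE, tol = NULL, max_iter = 10000L,
                     divergence_bound = 1e8) {
  err_type <- match.arg(err_type)
  if (!is.null(precision)) {
    stopifnot(inherits(precision, "pc_precision"))
    if (!is.null(precision$output) && loss$kind != "squared_euclidean") {
      pc_stop("pc_unsupported_error",
              "output precision is only supported with the squared-Euclidean loss")
    }
  }
  if (err_type != "exact") stopifnot(eta > 0, n >= 0)
  switch(err_type,
    exact = backprop_update(model, loss, x, y),
    strict = strict_pc_update(model, loss, x, y, eta = eta, n = n,
                              v_init = v_init, precision = precision,
                              refresh_errors = refresh_errors, tol = tol,
                              max_iter = max_iter,
                              divergence_bound = divergence_bound),
    fixed_pred = fixed_pred_pc_update(model, loss, x, y, eta = eta, n = n,
                                      v_init = v_init, precision = precision,
                                      tol = tol, max_iter = max_iter,
                                      divergence_bound = divergence_bound)
  )
}

#' Backpropagation reference update
#'
#' The standard backward recursion: `delta_L = dL/dvhat_L`,
#' `delta_l = delta_{l+1} . df_{l+1}(vhat_l)/dvhat_l`, and
#' `dtheta_l = -delta_l . df_l(vhat_{l-1})/dtheta_l`.
#'
#' @inheritParams pc_infer
#' @return A `pc_result`; `eps` holds the `delta_l` and `v` equals the
#'   forward activations.
#' @export
backprop_update <- function(model, loss, x, y) {
  L <- model$L
  vhat <- forward_pass(model, x)
  lg <- loss_and_output_grad(loss, vhat[[L + 1L]], y)
  eps <- vector("list", L)
  eps[[L]] <- lg$grad
  for (l in rev(seq_len(L - 1L))) {
    eps[[l]] <- layer_vjp_input(model$layers[[l + 1L]], vhat[[l + 1L]], eps[[l + 1L]])
  }
  dtheta <- vector("list", L)
  for (l in seq_len(L)) {
    g <- layer_vjp_params(model$layers[[l]], vhat[[l]], eps[[l]])
    dtheta[[l]] <- lapply(g, function(a) -a)
  }
  new_pc_result(vhat, lg$value, lg$grad, v = vhat[-1L], eps = eps,
                dtheta = dtheta, diagnostics = NULL,
                err_type = "exact", iters = 0L)
}

#' Strict predictive-coding update
#'
#' Direct gradient descent of the free energy on the beliefs; see
#' [pc_infer()] for the dynamics.  The parameter updates use the error
#' values left by the final inference sweep (pseudocode-literal) unless
#' `refresh_errors = TRUE`.
#'
#' @inheritParams pc_infer
#' @return A `pc_result`.  `v[[L]]` is set to the final prediction
#'   `vtilde_L = f_L(v_{L-1})`; diagnostics record per-iteration
#'   `max ||dv_l||_inf` per layer and the descent objective `F`.
#' @export
strict_pc_update <- function(model, loss, x, y, eta = 0.1, n = 20L,
                             v_init = NULL, precision = NULL,
                             refresh_errors = FALSE, tol = NULL,
                             max_iter = 10000L, divergence_bound = 1e8) {
  L <- model$L
  vhat <- forward_pass(model, x)
  lg <- loss_and_output_grad(loss, vhat[[L + 1L]], y)
  if (L == 1L) { # no hidden beliefs: identical to one backprop output step
    res <- backprop_update(model, loss, x, y)
    res$err_type <- "strict"
    return(res)
  }
  v <- v_init %||% vhat[-1L][seq_len(L - 1L)]
  stopifnot(length(v) >= L - 1L)
  v <- v[seq_len(L - 1L)]
  v <- lapply(v, as_batch)
  eps <- vector("list", L)
  n_iter <- if (is.null(tol)) n else max_iter
  diag_dv <- NULL
  diag_F <- numeric(0)
  iters_done <- 0L
  for (i in seq_len(n_iter)) {
    vtildeL <- layer_forward(model$layers[[L]], v[[L - 1L]])
    eps[[L]] <- loss_and_output_grad(loss, vtildeL, y)$grad
    eps[[L]] <- apply_precision(eps[[L]], if (is.null(precision)) NULL else precision$output)
    dv_inf <- numeric(L - 1L)
    for (l in rev(seq_len(L - 1L))) {
      v_prev <- if (l == 1L) vhat[[1L]] else v[[l - 1L]]
      eps[[l]] <- apply_precision(layer_forward(model$layers[[l]], v_prev) - v[[l]],
                                  hidden_precision(precision, l))
      dv <- eps[[l]] - layer_vjp_input(model$layers[[l + 1L]], v[[l]], eps[[l + 1L]])
      v[[l]] <- v[[l]] + eta * dv
      dv_inf[l] <- max(abs(dv))
    }
    check_divergence(v, divergence_bound, i)
    diag_dv <- rbind(diag_dv, dv_inf)
    diag_F <- c(diag_F, strict_objective(model, loss, x, y, v))
    iters_done <- i
    if (!is.null(tol) && max(dv_inf) < tol) break
  }
  if (refresh_errors && iters_done > 0L) {
    v_prev <- vhat[[1L]]
    for (l in seq_len(L - 1L)) {
      eps[[l]] <- apply_precision(layer_forward(model$layers[[l]], v_prev) - v[[l]],
                                  hidden_precision(precision, l))
      v_prev <- v[[l]]
    }
    vtildeL <- layer_forward(model$layers[[L]], v[[L - 1L]])
    eps[[L]] <- loss_and_output_grad(loss, vtildeL, y)$grad
    eps[[L]] <- apply_precision(eps[[L]], if (is.null(precision)) NULL else precision$output)
  }
  if (iters_done == 0L) { # n = 0: errors from the initial beliefs
    vtildeL <- layer_forward(model$layers[[L]], v[[L - 1L]])
    eps[[L]] <- loss_and_output_grad(loss, vtildeL, y)$grad
    eps[[L]] <- apply_precision(eps[[L]], if (is.null(precision)) NULL else precision$output)
    v_prev <- vhat[[1L]]
    for (l in seq_len(L - 1L)) {
      eps[[l]] <- apply_precision(layer_forward(model$layers[[l]], v_prev) - v[[l]],
                                  hidden_precision(precision, l))
      v_prev <- v[[l]]
    }
  }
  dtheta <- vector("list", L)
  for (l in seq_len(L)) {
    v_prev <- if (l == 1L) vhat[[1L]] else v[[l - 1L]]
    g <- layer_vjp_params(model$layers[[l]], v_prev, eps[[l]])
    dtheta[[l]] <- lapply(g, function(a) -a)
  }
  diagnostics <- NULL
  if (iters_done > 0L) {
    diagnostics <- data.frame(iter = seq_len(iters_done),
                              max_dv_inf = apply(diag_dv, 1L, max),
                              free_energy = diag_F)
    diagnostics$dv_inf <- unname(diag_dv)
  }
  v_out <- c(v, list(layer_forward(model$layers[[L]], v[[L - 1L]])))
  new_pc_result(vhat, lg$value, lg$grad, v = v_out, eps = eps, dtheta = dtheta,
                diagnostics = diagnostics, err_type = "strict",
                iters = iters_done)
}

#' Fixed-prediction predictive-coding update
#'
#' Predictive coding with predictions and Jacobian linearization points
#' frozen at the forward-pass activations (see [pc_infer()]).  The parameter
#' update uses the errors `eps_l = vhat_l - v_l` computed inside the final
#' inference sweep, exactly as in the pseudocode.  With `eta = 1` and
#' `n >= L` the result equals backpropagation exactly: each error is touched
#' once, on iteration `i = L - l + 1`, when it becomes `delta_l`.
#'
#' @inheritParams pc_infer
#' @return A `pc_result`; `v[[L]]` follows the convention
#'   `v_L = vhat_L - eps_L`.
#' @export
fixed_pred_pc_update <- function(model, loss, x, y, eta = 0.1, n = 20L,
                                 v_init = NULL, precision = NULL,
                                 tol = NULL, max_iter = 10000L,
                                 divergence_bound = 1e8) {
  L <- model$L
  vhat <- forward_pass(model, x)
  lg <- loss_and_output_grad(loss, vhat[[L + 1L]], y)
  epsL <- apply_precision(lg$grad, if (is.null(precision)) NULL else precision$output)
  eps <- vector("list", L)
  eps[[L]] <- epsL
  if (L == 1L) {
    g <- layer_vjp_params(model$layers[[1L]], vhat[[1L]], epsL)
    return(new_pc_result(vhat, lg$value, lg$grad, v = list(vhat[[2L]] - epsL),
                         eps = eps, dtheta = list(lapply(g, function(a) -a)),
                         diagnostics = NULL, err_type = "fixed_pred", iters = 0L))
  }
  v <- v_init %||% vhat[-1L][seq_len(L - 1L)]
  v <- lapply(v[seq_len(L - 1L)], as_batch)
  # Jacobian adjoints are frozen at vhat; precompute nothing, vjp is cheap here
  n_iter <- if (is.null(tol)) n else max_iter
  diag_dv <- NULL
  iters_done <- 0L
  for (i in seq_len(n_iter)) {
    dv_inf <- numeric(L - 1L)
    for (l in rev(seq_len(L - 1L))) {
      eps[[l]] <- apply_precision(vhat[[l + 1L]] - v[[l]], hidden_precision(precision, l))
      dv <- eps[[l]] - layer_vjp_input(model$layers[[l + 1L]], vhat[[l + 1L]], eps[[l + 1L]])
      v[[l]] <- v[[l]] + eta * dv
      dv_inf[l] <- max(abs(dv))
    }
    check_divergence(v, divergence_bound, i)
    diag_dv <- rbind(diag_dv, dv_inf)
    iters_done <- i
    if (!is.null(tol) && max(dv_inf) < tol) break
  }
  # the parameter loop uses the error values computed inside the final sweep
  # (pseudocode-literal): this is what makes the eta = 1 schedule complete at
  # exactly n = L, layer l becoming correct on iteration i = L - l + 1
  if (iters_done == 0L) {
    for (l in seq_len(L - 1L)) {
      eps[[l]] <- apply_precision(vhat[[l + 1L]] - v[[l]], hidden_precision(precision, l))
    }
  }
  dtheta <- vector("list", L)
  for (l in seq_len(L)) {
    g <- layer_vjp_params(model$layers[[l]], vhat[[l]], eps[[l]])
    dtheta[[l]] <- lapply(g, function(a) -a)
  }
  diagnostics <- NULL
  if (iters_done > 0L) {
    diagnostics <- data.frame(iter = seq_len(iters_done),
                              max_dv_inf = apply(diag_dv, 1L, max))
    diagnostics$dv_inf <- unname(diag_dv)
  }
  v_out <- c(v, list(vhat[[L + 1L]] - eps[[L]]))
  new_pc_result(vhat, lg$value, lg$grad, v = v_out, eps = eps, dtheta = dtheta,
                diagnostics = diagnostics, err_type = "fixed_pred",
                iters = iters_done)
}

#' Precision-weighted fixed-prediction update
#'
#' Convenience wrapper around [fixed_pred_pc_update()] with a
#' [precision_spec()].  With all precisions at identity the trajectory is
#' bit-identical to the unweighted algorithm; converged hidden precisions do
#' not change `dtheta`, while an output precision `P_L` rescales the
#' converged updates by `P_L`.
#'
#' @inheritParams pc_infer
#' @param precision A [precision_spec()].
#' @return A `pc_result`.
#' @export
precision_fixed_pred_update <- function(model, loss, x, y, precision,
                                        eta = 0.1, n = 20L, v_init = NULL,
                                        tol = NULL, max_iter = 10000L,
                                        divergence_bound = 1e8) {
  stopifnot(inherits(precision, "pc_precision"))
  if (!is.null(precision$output) && loss$kind != "squared_euclidean") {
    pc_stop("pc_unsupported_error",
            "output precision is only supported with the squared-Euclidean loss")
  }
  fixed_pred_pc_update(model, loss, x, y, eta = eta, n = n, v_init = v_init,
                       precision = precision, tol = tol, max_iter = max_iter,
                       divergence_bound = divergence_bound)
}
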