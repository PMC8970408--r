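#' Relative error between two update vectors
#'
#' `||a - b|| / ||b||` on the flattened parameter arrays (Euclidean norm);
#' `b` is the reference (typically the backpropagation update).
#'
#' @param dtheta_a,dtheta_b Arrays or (nested) lists of arrays with matching
#'   shapes.
#' @return Scalar relative error.
#' @export
relative_error <- function(dtheta_a, dtheta_b) {
  a <- unlist(dtheta_a, use.names = FALSE)
  b <- unlist(dtheta_b, use.names = FALSE)
  stopifnot(length(a) == length(b))
  nb <- sqrt(sum(b^2))
  if (nb == 0) pc_stop("pc_reference_error", "reference update has zero norm")
  sqrt(sum((a - b)^2)) / nb
}

#' Angle between two update vectors, in degrees
#'
#' Arccosine of the cosine similarity of the flattened updates, with the
#' cosine clipped to `[-1, 1]` to absorb round-off.
#'
#' @inheritParams relative_error
#' @return Angle in degrees, in `[0, 180]`.
#' @export
update_angle <- function(dtheta_a, dtheta_b) {
  a <- unlist(dtheta_a, use.names = FALSE)
  b <- unlist(dtheta_b, use.names = FALSE)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) pc_stop("pc_reference_error", "angle undefined for a zero vector")
  if (identical(a, b)) return(0) # avoid acos round-off for exact agreement
  cosim <- min(1, max(-1, sum(a * b) / (na * nb)))
  acos(cosim) * 180 / pi
}

#' Central finite-difference gradient oracle
#'
#' Independent gradient check: perturbs every scalar parameter by `+h` and
#' `-h`, re-runs the forward pass, and returns
#' `[L(theta + h e) - L(theta - h e)] / (2h)` per parameter.  This is the
#' positive gradient `+dL/dtheta`, i.e. the negative of the `dtheta`
#' returned by [backprop_update()].  Costs two forward passes per parameter,
#' so a parameter-count cap guards against misuse.
#'
#' @inheritParams pc_infer
#' @param h Step size for central differences.
#' @param max_params Refuse models with more parameters than this.
#' @return List of length `L` of named gradient arrays matching the model
#'   parameters (empty entries for parameter-free layers).
#' @export
finite_difference_grad <- function(model, loss, x, y, h = 1e-5, max_params = 2000L) {
  stopifnot(h > 0)
  fp <- flatten_model_params(model)
  P <- length(fp$vec)
  if (P > max_params) {
    pc_stop("pc_oracle_cap_error",
            "model has %d parameters, above the oracle cap of %d", P, max_params)
  }
  loss_at <- function(vec) {
    m2 <- set_model_params(model, unflatten_model_params(vec, fp$skeleton))
    vh <- forward_pass(m2, x)
    loss_and_output_grad(loss, vh[[length(vh)]], y)$value
  }
  g <- numeric(P)
  for (i in seq_len(P)) {
    vp <- fp$vec; vp[i] <- vp[i] + h
    vm <- fp$vec; vm[i] <- vm[i] - h
    g[i] <- (loss_at(vp) - loss_at(vm)) / (2 * h)
  }
  unflatten_model_params(g, fp$skeleton)
}

#' Fixed-point residuals of the prediction-error recursion
#'
#' At an inference fixed point the errors satisfy
#' `eps_l = eps_{l+1} . df_{l+1}(v_l)/dv_l`.  This measures the normalized
#' residual `||eps_l - eps_{l+1} J_{l+1}|| / max(||eps_l||, floor)` per
#' hidden layer, with the Jacobian linearized at the supplied points (the
#' beliefs for strict predictive coding, the forward activations for the
#' fixed prediction assumption).
#'
#' @param eps List of `L` prediction-error arrays.
#' @param model A `pc_network`.
#' @param points List of linearization points; `points[[l]]` is where
#'   `df_{l+1}/dv` is evaluated for `l = 1..L-1`.
#' @param floor Norm floor to keep the ratio defined for tiny errors.
#' @return Numeric vector of `L - 1` residuals.
#' @export
fixed_point_residual <- function(eps, model, points, floor = 1e-12) {
  L <- model$L
  stopifnot(length(eps) == L, length(points) >= L - 1L)
  res <- numeric(L - 1L)
  for (l in seq_len(L - 1L)) {
    pred <- layer_vjp_input(model$layers[[l + 1L]], points[[l]], eps[[l + 1L]])
    res[l] <- frob_norm(eps[[l]] - pred) / max(frob_norm(eps[[l]]), floor)
  }
  res
}

#' Sweep an algorithm over step sizes and iteration counts
#'
#' For each `(eta, n)` pair, runs the requested algorithm on one fixed
#' mini-batch and records the per-layer relative error and angle of its
#' `dtheta` against backpropagation, plus a whole-model aggregate row
#' (`layer = 0`).  Divergent strict-PC runs are recorded as flagged rows
#' with `NA` metrics rather than raised.
#'
#' @inheritParams pc_infer
#' @param etas Numeric vector of step sizes.
#' @param ns Integer vector of iteration counts.
#' @return Data frame with columns `eta`, `n`, `layer`, `relative_error`,
#'   `angle_deg`, `diverged`.
#' @export
sweep_compare <- function(model, loss, x, y, err_type = "fixed_pred",
                          etas = c(0.1, 0.5, 1), ns = c(1, 5, 20),
                          precision = NULL) {
  bp <- backprop_update(model, loss, x, y)
  has_params <- vapply(bp$dtheta, function(d) length(d) > 0L, TRUE)
  rows <- list()
  for (eta in etas) for (n in ns) {
    res <- tryCatch(
      pc_infer(model, loss, x, y, err_type = err_type, eta = eta, n = n,
               precision = precision),
      pc_divergence_error = function(e) NULL
    )
    for (l in c(0L, which(has_params))) {
      if (is.null(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          eta = eta, n = n, layer = l,
          relative_error = NA_real_, angle_deg = NA_real_, diverged = TRUE)
      } else {
        da <- if (l == 0L) res$dtheta[has_params] else res$dtheta[[l]]
        db <- if (l == 0L) bp$dtheta[has_params] else bp$dtheta[[l]]
        # an all-zero pc update (early iterations) has no defined angle
        ang <- tryCatch(update_angle(da, db),
                        pc_reference_error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          eta = eta, n = n, layer = l,
          relative_error = relative_error(da, db),
          angle_deg = ang, diverged = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
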