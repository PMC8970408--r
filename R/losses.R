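#' Loss functions
#'
#' Both losses use mean-over-batch reduction, so the output gradient carries
#' a factor 1/m and parameter updates are invariant to batch size.
#'
#' * `loss_squared_euclidean()`: `L = (1/m) * sum_b (1/2) ||yhat_b - y_b||^2`,
#'   gradient `(yhat - y)/m`.  Targets must have the shape of the output
#'   (e.g. one-hot rows for classification).
#' * `loss_softmax_cross_entropy()`: treats the network output as logits;
#'   `L = (1/m) * sum_b (logsumexp(z_b) - z_b[y_b])`, gradient
#'   `(softmax(z) - Y)/m`.  Targets may be 1-based class indices or one-hot
#'   rows.
#'
#' @return A `pc_loss` object usable by [loss_and_output_grad()] and the
#'   algorithm drivers.
#' @name losses
NULL

#' @rdname losses
#' @export
loss_squared_euclidean <- function() {
  structure(list(kind = "squared_euclidean"), class = "pc_loss")
}

#' @rdname losses
#' @export
loss_softmax_cross_entropy <- function() {
  structure(list(kind = "softmax_cross_entropy"), class = "pc_loss")
}

loss_from_name <- function(kind) {
  switch(kind,
    squared_euclidean = loss_squared_euclidean(),
    softmax_cross_entropy = loss_softmax_cross_entropy(),
    pc_stop("pc_config_error", "unknown loss kind '%s'", kind))
}

# targets as a dense matrix matching y_hat (one-hot if class indices given)
loss_targets <- function(y, K, m) {
  if (is.null(dim(y)) && length(y) == m && K > 1L) {
    return(one_hot(y, K))
  }
  as_batch(y)
}

#' Loss value and output gradient
#'
#' Evaluates the loss under mean-over-batch reduction and its gradient with
#' respect to the prediction, `dL/dyhat`, which has the shape of `yhat` and
#' serves as the output-layer prediction error.
#'
#' @param loss A `pc_loss`.
#' @param y_hat Prediction batch `(m, K)`.
#' @param y Target batch `(m, K)`, or for cross-entropy a length-`m` vector
#'   of 1-based class indices.
#' @return List with `value` (scalar) and `grad` (array shaped like `y_hat`).
#' @export
loss_and_output_grad <- function(loss, y_hat, y) {
  stopifnot(inherits(loss, "pc_loss"))
  y_hat <- as_batch(y_hat)
  check_finite(y_hat, "y_hat")
  m <- dim(y_hat)[1L]
  if (loss$kind == "squared_euclidean") {
    y <- loss_targets(y, dim(y_hat)[2L], m)
    if (!identical(dim(y), dim(y_hat))) {
      pc_stop("pc_shape_error", "y_hat and y shapes differ")
    }
    check_finite(y, "y")
    d <- y_hat - y
    list(value = sum(d^2) / (2 * m), grad = d / m)
  } else { # softmax cross entropy on logits
    K <- dim(y_hat)[2L]
    Y <- loss_targets(y, K, m)
    if (!identical(dim(Y), dim(y_hat))) {
      pc_stop("pc_shape_error", "y_hat and y shapes differ")
    }
    check_finite(Y, "y")
    zmax <- apply(y_hat, 1L, max)
    zc <- y_hat - zmax
    lse <- log(rowSums(exp(zc))) + zmax
    p <- exp(zc) / rowSums(exp(zc))
    list(value = sum(lse - rowSums(y_hat * Y)) / m, grad = (p - Y) / m)
  }
}
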