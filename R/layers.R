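#' @title Network layers
#' @description
#' A layer is one differentiable stage `f(v; theta)` of a feedforward chain.
#' Every layer implements three contracts: a forward map, a vector-Jacobian
#' product with respect to its input, and a vector-Jacobian product with
#' respect to its parameters.  Adjoints are row-form: the cotangent `a` has
#' the shape of the layer output (batch leading dimension) and the results
#' are `a %*% df/dv` and `a %*% df/dtheta` without ever materializing a
#' Jacobian.  All activations are arrays with a leading batch dimension:
#' `(m, n)` for vector layers, `(m, C, H, W)` for image layers.
#' @name layers
NULL

new_layer <- function(kind, input_shape, output_shape, theta = list(), extra = list()) {
  structure(
    c(list(kind = kind,
           input_shape = as.integer(input_shape),
           output_shape = as.integer(output_shape),
           theta = theta),
      extra),
    class = c(paste0("layer_", kind), "pc_layer")
  )
}

# fan-in scaled uniform initialization; draws from the current RNG stream
init_uniform <- function(dims, fan_in) {
  s <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -s, s), dims)
}

#' Fully connected (affine) layer
#'
#' Computes `v %*% W + b` on a batch `v` of shape `(m, n_in)`.
#'
#' @param n_in,n_out Input and output widths.
#' @param W Optional `n_in x n_out` weight matrix.
#' @param b Optional length-`n_out` bias vector.
#' @param seed Optional seed for fan-in scaled uniform initialization of any
#'   parameter not supplied; if `NULL`, the current RNG stream is used.
#' @return A `pc_layer` object.
#' @export
layer_affine <- function(n_in, n_out, W = NULL, b = NULL, seed = NULL) {
  make <- function() {
    if (is.null(W)) W <<- init_uniform(c(n_in, n_out), n_in)
    if (is.null(b)) b <<- as.numeric(init_uniform(n_out, n_in))
  }
  if (is.null(seed)) make() else with_seed(seed, make())
  stopifnot(all(dim(W) == c(n_in, n_out)), length(b) == n_out)
  new_layer("affine", n_in, n_out, theta = list(W = W, b = b))
}

#' 2-d convolution layer (stride 1, no padding)
#'
#' Cross-correlation of a `(m, C, H, W)` batch with an
#' `(out_channels, C, kh, kw)` kernel plus a per-channel bias.  Implemented
#' by im2col and a single matrix product; built for correctness at small
#' shapes rather than speed.
#'
#' @param in_shape Integer vector `c(C, H, W)`.
#' @param out_channels Number of output channels.
#' @param kernel Integer vector `c(kh, kw)` (a scalar is recycled).
#' @param W Optional kernel array `(out_channels, C, kh, kw)`.
#' @param b Optional length-`out_channels` bias.
#' @param seed Optional initialization seed (see [layer_affine()]).
#' @return A `pc_layer` object.
#' @export
layer_conv2d <- function(in_shape, out_channels, kernel, W = NULL, b = NULL, seed = NULL) {
  stopifnot(length(in_shape) == 3L)
  if (length(kernel) == 1L) kernel <- c(kernel, kernel)
  C <- in_shape[1]; H <- in_shape[2]; Wd <- in_shape[3]
  kh <- kernel[1]; kw <- kernel[2]
  oh <- H - kh + 1L; ow <- Wd - kw + 1L
  if (oh < 1L || ow < 1L) pc_stop("pc_shape_error", "kernel larger than input")
  fan_in <- C * kh * kw
  make <- function() {
    if (is.null(W)) W <<- init_uniform(c(out_channels, C, kh, kw), fan_in)
    if (is.null(b)) b <<- as.numeric(init_uniform(out_channels, fan_in))
  }
  if (is.null(seed)) make() else with_seed(seed, make())
  stopifnot(all(dim(W) == c(out_channels, C, kh, kw)), length(b) == out_channels)
  new_layer("conv2d", in_shape, c(out_channels, oh, ow),
            theta = list(W = W, b = b),
            extra = list(kernel = c(kh, kw)))
}

#' Rectified linear unit layer
#'
#' Elementwise `max(v, 0)`; the subgradient at 0 is taken to be 0.
#'
#' @param shape Integer vector giving the (batch-free) activation shape.
#' @return A `pc_layer` object.
#' @export
layer_relu <- function(shape) new_layer("relu", shape, shape)

#' Hyperbolic tangent layer
#'
#' @inheritParams layer_relu
#' @return A `pc_layer` object.
#' @export
layer_tanh <- function(shape) new_layer("tanh", shape, shape)

#' Flatten layer
#'
#' Reshapes `(m, C, H, W)` (or any higher-rank) activations to `(m, prod)`.
#'
#' @param in_shape Integer vector of input activation shape.
#' @return A `pc_layer` object.
#' @export
layer_flatten <- function(in_shape) new_layer("flatten", in_shape, prod(in_shape))

#' Composite block layer
#'
#' Wraps an ordered list of sub-layers into a single predictive-coding layer:
#' the block is treated as one stage `f`, with beliefs and prediction errors
#' attached only to its final output.  Parameters of the sub-layers are
#' exposed with names `"<index>.<name>"`.
#'
#' @param layers List of `pc_layer` objects with chained shapes.
#' @return A `pc_layer` object.
#' @export
layer_block <- function(layers) {
  stopifnot(length(layers) >= 1L, all(vapply(layers, inherits, TRUE, "pc_layer")))
  for (j in seq_len(length(layers) - 1L)) {
    if (!identical(layers[[j]]$output_shape, layers[[j + 1L]]$input_shape)) {
      pc_stop("pc_shape_error", "block sub-layer %d output does not match sub-layer %d input", j, j + 1L)
    }
  }
  new_layer("block", layers[[1L]]$input_shape, layers[[length(layers)]]$output_shape,
            theta = list(), extra = list(layers = layers))
}

# ---- generics ----------------------------------------------------------

#' Apply a layer's forward map to a batch
#'
#' @param layer A `pc_layer`.
#' @param v Input batch with dim `(m, input_shape)`.
#' @return Output batch with dim `(m, output_shape)`.
#' @export
layer_forward <- function(layer, v) UseMethod("layer_forward")

#' Vector-Jacobian product with respect to the layer input
#'
#' Returns `a . df(v_in; theta)/dv_in` evaluated at the linearization point
#' `v_in`, for a row-adjoint `a` shaped like the layer output.  Linear in `a`;
#' no Jacobian is formed.
#'
#' @param layer A `pc_layer`.
#' @param v_in Input batch at which the Jacobian is taken.
#' @param a Row-adjoint with the shape of the layer output.
#' @return Row-adjoint with the shape of the layer input.
#' @export
layer_vjp_input <- function(layer, v_in, a) UseMethod("layer_vjp_input")

#' Vector-Jacobian product with respect to the layer parameters
#'
#' Returns `a . df(v_in; theta)/dtheta` summed over the batch, one array per
#' named parameter.  The 1/m of a mean-over-batch loss lives in the output
#' adjoint produced by [loss_and_output_grad()], so no additional batch
#' division happens here.  Parameter-free layers return an empty list.
#'
#' @inheritParams layer_vjp_input
#' @return Named list of arrays matching `layer$theta` shapes.
#' @export
layer_vjp_params <- function(layer, v_in, a) UseMethod("layer_vjp_params")

# named list of parameter arrays (flattened with "<i>.<name>" for blocks)
layer_params <- function(layer) UseMethod("layer_params")
set_layer_params <- function(layer, params) UseMethod("set_layer_params")

#' @export
layer_params.pc_layer <- function(layer) layer$theta
#' @export
set_layer_params.pc_layer <- function(layer, params) {
  stopifnot(identical(names(params), names(layer$theta)))
  for (nm in names(params)) stopifnot(length(params[[nm]]) == length(layer$theta[[nm]]))
  layer$theta <- params
  layer
}

check_vjp_shapes <- function(layer, v_in, a) {
  v_in <- as_batch(v_in, layer$input_shape)
  a <- as_batch(a, layer$output_shape)
  check_finite(v_in, "v_in"); check_finite(a, "adjoint")
  list(v_in = v_in, a = a)
}

# ---- affine ------------------------------------------------------------

#' @export
layer_forward.layer_affine <- function(layer, v) {
  v <- as_batch(v, layer$input_shape)
  out <- v %*% layer$theta$W
  out + rep(layer$theta$b, each = nrow(out))
}

#' @export
layer_vjp_input.layer_affine <- function(layer, v_in, a) {
  a <- as_batch(a, layer$output_shape)
  check_finite(a, "adjoint")
  a %*% t(layer$theta$W)
}

#' @export
layer_vjp_params.layer_affine <- function(layer, v_in, a) {
  s <- check_vjp_shapes(layer, v_in, a)
  list(W = t(s$v_in) %*% s$a, b = colSums(s$a))
}

# ---- pointwise nonlinearities -----------------------------------------

#' @export
layer_forward.layer_relu <- function(layer, v) {
  v <- as_batch(v, layer$input_shape)
  pmax(v, 0)
}

#' @export
layer_vjp_input.layer_relu <- function(layer, v_in, a) {
  s <- check_vjp_shapes(layer, v_in, a)
  s$a * (s$v_in > 0)
}

#' @export
layer_vjp_params.layer_relu <- function(layer, v_in, a) list()

#' @export
layer_forward.layer_tanh <- function(layer, v) {
  v <- as_batch(v, layer$input_shape)
  tanh(v)
}

#' @export
layer_vjp_input.layer_tanh <- function(layer, v_in, a) {
  s <- check_vjp_shapes(layer, v_in, a)
  s$a * (1 - tanh(s$v_in)^2)
}

#' @export
layer_vjp_params.layer_tanh <- function(layer, v_in, a) list()

# ---- flatten -----------------------------------------------------------

#' @export
layer_forward.layer_flatten <- function(layer, v) {
  v <- as_batch(v, layer$input_shape)
  m <- dim(v)[1L]
  dim(v) <- c(m, prod(layer$input_shape))
  v
}

#' @export
layer_vjp_input.layer_flatten <- function(layer, v_in, a) {
  a <- as_batch(a, layer$output_shape)
  dim(a) <- c(dim(a)[1L], layer$input_shape)
  a
}

#' @export
layer_vjp_params.layer_flatten <- function(layer, v_in, a) list()

# ---- conv2d ------------------------------------------------------------

# patch matrix: rows index (batch, oh, ow), columns index (C, kh, kw)
conv_im2col <- function(x, kh, kw, oh, ow) {
  d <- dim(x); m <- d[1L]; C <- d[2L]
  Xc <- array(0, c(m, C, kh, kw, oh, ow))
  for (ih in seq_len(kh)) for (iw in seq_len(kw)) {
    Xc[, , ih, iw, , ] <- x[, , ih:(ih + oh - 1L), iw:(iw + ow - 1L), drop = FALSE]
  }
  Xc <- aperm(Xc, c(1L, 5L, 6L, 2L, 3L, 4L))
  dim(Xc) <- c(m * oh * ow, C * kh * kw)
  Xc
}

conv_kernel_matrix <- function(W) {
  d <- dim(W) # (OC, C, kh, kw)
  Wm <- aperm(W, c(2L, 3L, 4L, 1L))
  dim(Wm) <- c(prod(d[2:4]), d[1L])
  Wm
}

#' @export
layer_forward.layer_conv2d <- function(layer, v) {
  v <- as_batch(v, layer$input_shape)
  m <- dim(v)[1L]
  k <- layer$kernel
  os <- layer$output_shape # (OC, oh, ow)
  Xc <- conv_im2col(v, k[1L], k[2L], os[2L], os[3L])
  Y <- Xc %*% conv_kernel_matrix(layer$theta$W)
  Y <- Y + rep(layer$theta$b, each = nrow(Y))
  dim(Y) <- c(m, os[2L], os[3L], os[1L])
  aperm(Y, c(1L, 4L, 2L, 3L))
}

#' @export
layer_vjp_input.layer_conv2d <- function(layer, v_in, a) {
  s <- check_vjp_shapes(layer, v_in, a)
  m <- dim(s$a)[1L]
  k <- layer$kernel; kh <- k[1L]; kw <- k[2L]
  os <- layer$output_shape; oh <- os[2L]; ow <- os[3L]
  is <- layer$input_shape
  Am <- aperm(s$a, c(1L, 3L, 4L, 2L))
  dim(Am) <- c(m * oh * ow, os[1L])
  Ac <- Am %*% t(conv_kernel_matrix(layer$theta$W))
  dim(Ac) <- c(m, oh, ow, is[1L], kh, kw)
  Ac <- aperm(Ac, c(1L, 4L, 5L, 6L, 2L, 3L)) # (m, C, kh, kw, oh, ow)
  dx <- array(0, c(m, is))
  for (ih in seq_len(kh)) for (iw in seq_len(kw)) {
    patch <- Ac[, , ih, iw, , , drop = FALSE]
    dim(patch) <- c(m, is[1L], oh, ow)
    cur <- dx[, , ih:(ih + oh - 1L), iw:(iw + ow - 1L), drop = FALSE]
    dim(cur) <- dim(patch)
    dx[, , ih:(ih + oh - 1L), iw:(iw + ow - 1L)] <- cur + patch
  }
  dx
}

#' @export
layer_vjp_params.layer_conv2d <- function(layer, v_in, a) {
  s <- check_vjp_shapes(layer, v_in, a)
  m <- dim(s$a)[1L]
  k <- layer$kernel
  os <- layer$output_shape; oh <- os[2L]; ow <- os[3L]
  is <- layer$input_shape
  Xc <- conv_im2col(s$v_in, k[1L], k[2L], oh, ow)
  Am <- aperm(s$a, c(1L, 3L, 4L, 2L))
  dim(Am) <- c(m * oh * ow, os[1L])
  dWm <- t(Xc) %*% Am # (C*kh*kw, OC)
  dim(dWm) <- c(is[1L], k[1L], k[2L], os[1L])
  list(W = aperm(dWm, c(4L, 1L, 2L, 3L)), b = colSums(Am))
}

# ---- block -------------------------------------------------------------

block_forward_trace <- function(layer, v) {
  vs <- vector("list", length(layer$layers) + 1L)
  vs[[1L]] <- v
  for (j in seq_along(layer$layers)) {
    vs[[j + 1L]] <- layer_forward(layer$layers[[j]], vs[[j]])
  }
  vs
}

#' @export
layer_forward.layer_block <- function(layer, v) {
  vs <- block_forward_trace(layer, as_batch(v, layer$input_shape))
  vs[[length(vs)]]
}

#' @export
layer_vjp_input.layer_block <- function(layer, v_in, a) {
  vs <- block_forward_trace(layer, as_batch(v_in, layer$input_shape))
  for (j in rev(seq_along(layer$layers))) {
    a <- layer_vjp_input(layer$layers[[j]], vs[[j]], a)
  }
  a
}

#' @export
layer_vjp_params.layer_block <- function(layer, v_in, a) {
  vs <- block_forward_trace(layer, as_batch(v_in, layer$input_shape))
  out <- list()
  adj <- vector("list", length(layer$layers))
  adj[[length(layer$layers)]] <- a
  for (j in rev(seq_along(layer$layers))) {
    if (j > 1L) adj[[j - 1L]] <- layer_vjp_input(layer$layers[[j]], vs[[j]], adj[[j]])
  }
  for (j in seq_along(layer$layers)) {
    g <- layer_vjp_params(layer$layers[[j]], vs[[j]], adj[[j]])
    if (length(g)) names(g) <- paste0(j, ".", names(g))
    out <- c(out, g)
  }
  out
}

#' @export
layer_params.layer_block <- function(layer) {
  out <- list()
  for (j in seq_along(layer$layers)) {
    p <- layer_params(layer$layers[[j]])
    if (length(p)) names(p) <- paste0(j, ".", names(p))
    out <- c(out, p)
  }
  out
}

#' @export
set_layer_params.layer_block <- function(layer, params) {
  for (j in seq_along(layer$layers)) {
    p <- layer_params(layer$layers[[j]])
    if (!length(p)) next
    sub <- params[paste0(j, ".", names(p))]
    names(sub) <- names(p)
    layer$layers[[j]] <- set_layer_params(layer$layers[[j]], sub)
  }
  layer
}

#' @export
print.pc_layer <- function(x, ...) {
  cat(sprintf("<pc_layer %s: (%s) -> (%s), %d parameters>\n",
              x$kind,
              paste(x$input_shape, collapse = "x"),
              paste(x$output_shape, collapse = "x"),
              length(flatten_arrays(layer_params(x)))))
  invisible(x)
}
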