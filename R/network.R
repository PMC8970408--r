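#' Feedforward network model
#'
#' A network is an ordered chain of layers `f_1, ..., f_L`; the forward pass
#' computes `vhat_0 = x`, `vhat_l = f_l(vhat_{l-1}; theta_l)`.  Shapes are
#' validated end to end at construction.
#'
#' @param layers List of `pc_layer` objects (see [layer_affine()],
#'   [layer_conv2d()], [layer_relu()], [layer_tanh()], [layer_flatten()],
#'   [layer_block()]).
#' @return A `pc_network` object with fields `layers` and depth `L`.
#' @export
network <- function(layers) {
  stopifnot(length(layers) >= 1L, all(vapply(layers, inherits, TRUE, "pc_layer")))
  for (l in seq_len(length(layers) - 1L)) {
    if (!identical(layers[[l]]$output_shape, layers[[l + 1L]]$input_shape)) {
      pc_stop("pc_shape_error",
              "layer %d output shape (%s) does not match layer %d input shape (%s)",
              l, paste(layers[[l]]$output_shape, collapse = "x"),
              l + 1L, paste(layers[[l + 1L]]$input_shape, collapse = "x"))
    }
  }
  structure(list(layers = layers, L = length(layers)), class = "pc_network")
}

#' @export
print.pc_network <- function(x, ...) {
  cat(sprintf("<pc_network: depth %d, %d parameters>\n", x$L, n_params(x)))
  for (l in seq_len(x$L)) {
    cat(sprintf("  [%d] ", l)); print(x$layers[[l]])
  }
  invisible(x)
}

#' Forward pass through a network
#'
#' @param model A `pc_network`.
#' @param x Input batch with dim `(m, input_shape)` (a plain vector is
#'   treated as a single sample).
#' @return List of `L + 1` activation batches `vhat_0 = x, ..., vhat_L`.
#' @export
forward_pass <- function(model, x) {
  x <- as_batch(x)
  if (!identical(as.integer(dim(x)[-1L]), model$layers[[1L]]$input_shape)) {
    pc_stop("pc_shape_error", "input shape (%s) does not match layer 1 input shape (%s)",
            paste(dim(x)[-1L], collapse = "x"),
            paste(model$layers[[1L]]$input_shape, collapse = "x"))
  }
  check_finite(x, "input")
  vhat <- vector("list", model$L + 1L)
  vhat[[1L]] <- x
  for (l in seq_len(model$L)) {
    vhat[[l + 1L]] <- layer_forward(model$layers[[l]], vhat[[l]])
  }
  vhat
}

#' Get or set all model parameters
#'
#' `model_params()` returns a list (one element per layer) of named lists of
#' parameter arrays; `set_model_params()` writes such a structure back.
#'
#' @param model A `pc_network`.
#' @return For `model_params()`, a list of length `L`.
#' @export
model_params <- function(model) lapply(model$layers, layer_params)

#' @rdname model_params
#' @param params Structure as returned by `model_params()`.
#' @export
set_model_params <- function(model, params) {
  stopifnot(length(params) == model$L)
  for (l in seq_len(model$L)) {
    if (length(params[[l]])) {
      model$layers[[l]] <- set_layer_params(model$layers[[l]], params[[l]])
    }
  }
  model
}

#' Total number of trainable parameters
#' @param model A `pc_network`.
#' @return Integer count.
#' @export
n_params <- function(model) length(flatten_arrays(model_params(model)))

# flatten all parameters to one vector plus a skeleton for the inverse
flatten_model_params <- function(model) {
  params <- model_params(model)
  list(vec = unlist(lapply(params, flatten_arrays), use.names = FALSE),
       skeleton = params)
}

unflatten_model_params <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  for (l in seq_along(skeleton)) {
    n <- length(flatten_arrays(skeleton[[l]]))
    out[[l]] <- unflatten_arrays(vec[pos + seq_len(n)], skeleton[[l]])
    pos <- pos + n
  }
  out
}

# ---- JSON model descriptions and parameter checkpoints ----------------

layer_from_spec <- function(spec) {
  kind <- spec$kind %||% pc_stop("pc_config_error", "layer spec missing 'kind'")
  seed <- spec$seed
  switch(kind,
    affine = layer_affine(spec$n_in, spec$n_out, seed = seed),
    conv2d = layer_conv2d(unlist(spec$in_shape), spec$out_channels,
                          unlist(spec$kernel), seed = seed),
    relu = layer_relu(unlist(spec$shape)),
    tanh = layer_tanh(unlist(spec$shape)),
    flatten = layer_flatten(unlist(spec$in_shape)),
    block = layer_block(lapply(spec$layers, layer_from_spec)),
    pc_stop("pc_config_error", "unknown layer kind '%s'", kind)
  )
}

#' Build a network from a list/JSON description
#'
#' The description is a list with an ordered `layers` field; each entry is a
#' list with a `kind` (`affine`, `conv2d`, `relu`, `tanh`, `flatten`,
#' `block`) and the constructor's shape fields, plus an optional per-layer
#' `seed`.  A top-level `seed` initializes any layer without its own.
#'
#' @param spec List (e.g. parsed from JSON with
#'   `jsonlite::fromJSON(..., simplifyVector = FALSE)`).
#' @param seed Optional default initialization seed.
#' @return A `pc_network`.
#' @export
model_from_spec <- function(spec, seed = NULL) {
  if (is.null(spec$layers)) pc_stop("pc_config_error", "model spec missing 'layers'")
  seed <- spec$seed %||% seed
  build <- function() network(lapply(spec$layers, layer_from_spec))
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Read a model description from a JSON file
#' @param path Path to a JSON model description (see [model_from_spec()]).
#' @param seed Optional default initialization seed.
#' @return A `pc_network`.
#' @export
read_model_json <- function(path, seed = NULL) {
  model_from_spec(jsonlite::fromJSON(path, simplifyVector = FALSE), seed = seed)
}

#' Save or load model parameters as a JSON checkpoint
#'
#' The checkpoint is a plain-text JSON archive: one named entry per layer,
#' each holding named arrays stored as `{dim, values}` at full double
#' precision.
#'
#' @param model A `pc_network`.
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the model with parameters replaced.
#' @export
save_checkpoint <- function(model, path) {
  params <- model_params(model)
  enc <- lapply(params, function(p) {
    lapply(p, function(a) list(dim = as.integer(dim(a) %||% length(a)),
                               values = as.numeric(a)))
  })
  jsonlite::write_json(enc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  enc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  params <- model_params(model)
  stopifnot(length(enc) == length(params))
  for (l in seq_along(params)) {
    for (nm in names(params[[l]])) {
      a <- enc[[l]][[nm]]
      vals <- as.numeric(unlist(a$values))
      stopifnot(length(vals) == length(params[[l]][[nm]]))
      if (!is.null(dim(params[[l]][[nm]]))) dim(vals) <- dim(params[[l]][[nm]])
      params[[l]][[nm]] <- vals
    }
  }
  set_model_params(model, params)
}
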