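#' Training configuration
#'
#' @param err_type Algorithm whose output feeds the optimizer: `"exact"`
#'   (backpropagation), `"strict"`, or `"fixed_pred"`.
#' @param eta Inference step size for the predictive-coding algorithms.
#' @param n Inference iterations; `NULL` means `L` (the network depth),
#'   the natural choice for `fixed_pred` with `eta = 1`.
#' @param optimizer `"sgd"` or `"adam"`.
#' @param learning_rate Optimizer learning rate (eta_theta).
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param seed Mandatory seed; the only source of randomness in [train()]
#'   (mini-batch shuffling).
#' @param eval_every Log metrics every this many optimizer steps (the final
#'   step is always logged).
#' @param loss A `pc_loss`; defaults to squared-Euclidean on one-hot targets.
#' @param precision Optional [precision_spec()] forwarded to the algorithm.
#' @return A `pc_train_config` list.
#' @export
train_config <- function(err_type = "exact", eta = 0.1, n = NULL,
                         optimizer = c("adam", "sgd"), learning_rate = 1e-3,
                         batch_size = 32L, epochs = 1L, seed,
                         eval_every = 10L, loss = loss_squared_euclidean(),
                         precision = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 0L, eval_every >= 1L)
  if (missing(seed)) pc_stop("pc_config_error", "train_config requires a seed")
  structure(list(err_type = err_type, eta = eta, n = n, optimizer = optimizer,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 eval_every = as.integer(eval_every), loss = loss,
                 precision = precision),
            class = "pc_train_config")
}

#' Optimizer state and step
#'
#' `optimizer_init()` builds state for SGD or Adam over a flat parameter
#' vector; `optimizer_step()` consumes the gradient `g = -dtheta` (so the
#' predictive-coding update `dtheta`, returned in the negative-gradient
#' sense, is fed in negated) and returns updated parameters and state.
#' SGD: `theta <- theta - lr * g`.  Adam uses the standard first/second
#' moment estimates with bias correction (beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8).
#'
#' @param kind `"sgd"` or `"adam"`.
#' @param learning_rate Step size.
#' @param n_params Length of the parameter vector.
#' @return `optimizer_init()`: an opaque state list. `optimizer_step()`: a
#'   list with `params` and `state`.
#' @export
optimizer_init <- function(kind = c("sgd", "adam"), learning_rate, n_params) {
  kind <- match.arg(kind)
  state <- list(kind = kind, lr = learning_rate, t = 0L)
  if (kind == "adam") {
    state$m <- numeric(n_params)
    state$v <- numeric(n_params)
    state$beta1 <- 0.9; state$beta2 <- 0.999; state$eps <- 1e-8
  }
  state
}

#' @rdname optimizer_init
#' @param state State from `optimizer_init()` or a previous step.
#' @param params Flat numeric parameter vector.
#' @param grad Flat gradient vector (`-dtheta`).
#' @export
optimizer_step <- function(state, params, grad) {
  stopifnot(length(params) == length(grad))
  if (!all(is.finite(grad))) {
    pc_stop("pc_numeric_error", "non-finite update passed to the optimizer")
  }
  state$t <- state$t + 1L
  if (state$kind == "sgd") {
    params <- params - state$lr * grad
  } else {
    state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
    state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
    mhat <- state$m / (1 - state$beta1^state$t)
    vhat <- state$v / (1 - state$beta2^state$t)
    params <- params - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

#' Evaluate a model on a dataset
#'
#' Accuracy is the fraction of samples whose argmax output matches the
#' label; ties break to the lowest class index.  No parameters are mutated.
#'
#' @param model A `pc_network`.
#' @param dataset A `pc_dataset`.
#' @param loss A `pc_loss`.
#' @return List with `loss` and `accuracy`.
#' @export
evaluate <- function(model, dataset, loss = loss_squared_euclidean()) {
  stopifnot(inherits(dataset, "pc_dataset"))
  m <- dim(as_batch(dataset$x))[1L]
  if (m == 0L) pc_stop("pc_data_error", "cannot evaluate on an empty dataset")
  vhat <- forward_pass(model, dataset$x)
  out <- vhat[[length(vhat)]]
  lg <- loss_and_output_grad(loss, out,
                             if (loss$kind == "squared_euclidean") dataset$y else dataset$labels)
  pred <- apply(out, 1L, which.max) # which.max breaks ties at the lowest index
  list(loss = lg$value, accuracy = mean(pred == dataset$labels))
}

#' Mini-batch training driver
#'
#' Trains `model` on `train_data` by feeding the selected algorithm's
#' `dtheta` into the optimizer (`theta <- theta + eta_theta * dtheta` for
#' SGD; Adam receives `-dtheta` as its gradient).  Deterministic given the
#' config seed: identical configs yield identical metric logs.
#'
#' @param model A `pc_network`.
#' @param train_data A `pc_dataset`.
#' @param cfg A [train_config()].
#' @param test_data Optional held-out `pc_dataset` for test metrics
#'   (generate it with a disjoint seed).
#' @return List with `model` (trained) and `metrics`, a data frame with
#'   columns `step`, `train_loss`, `train_accuracy`, `test_loss`,
#'   `test_accuracy` (`NA` without `test_data`).
#' @export
train <- function(model, train_data, cfg, test_data = NULL) {
  stopifnot(inherits(cfg, "pc_train_config"), inherits(train_data, "pc_dataset"))
  loss <- cfg$loss
  m <- dim(as_batch(train_data$x))[1L]
  n_inf <- cfg$n %||% model$L
  fp <- flatten_model_params(model)
  opt <- optimizer_init(cfg$optimizer, cfg$learning_rate, length(fp$vec))
  params <- fp$vec
  metrics <- list()
  step <- 0L
  log_row <- function() {
    cur <- set_model_params(model, unflatten_model_params(params, fp$skeleton))
    tr <- evaluate(cur, train_data, loss)
    te <- if (is.null(test_data)) list(loss = NA_real_, accuracy = NA_real_)
          else evaluate(cur, test_data, loss)
    data.frame(step = step, train_loss = tr$loss, train_accuracy = tr$accuracy,
               test_loss = te$loss, test_accuracy = te$accuracy)
  }
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(m)
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      for (b in batches) {
        cur <- set_model_params(model, unflatten_model_params(params, fp$skeleton))
        xb <- extract_batch(train_data$x, b)
        yb <- if (loss$kind == "squared_euclidean") train_data$y[b, , drop = FALSE]
              else train_data$labels[b]
        res <- pc_infer(cur, loss, xb, yb, err_type = cfg$err_type,
                        eta = cfg$eta, n = n_inf, precision = cfg$precision)
        grad <- -unlist(lapply(res$dtheta, flatten_arrays), use.names = FALSE)
        if (length(grad) == 0L) grad <- numeric(length(params))
        st <- optimizer_step(opt, params, grad)
        params <- st$params; opt <- st$state
        step <- step + 1L
        if (step %% cfg$eval_every == 0L) metrics[[length(metrics) + 1L]] <- log_row()
      }
    }
  })
  if (step > 0L && (step %% cfg$eval_every != 0L)) {
    metrics[[length(metrics) + 1L]] <- log_row()
  }
  final <- set_model_params(model, unflatten_model_params(params, fp$skeleton))
  metrics <- if (length(metrics)) do.call(rbind, metrics)
             else data.frame(step = integer(0), train_loss = numeric(0),
                             train_accuracy = numeric(0), test_loss = numeric(0),
                             test_accuracy = numeric(0))
  list(model = final, metrics = metrics)
}

# index the batch dimension of an activation array of any rank
extract_batch <- function(x, idx) {
  d <- dim(as_batch(x))
  if (length(d) == 2L) return(x[idx, , drop = FALSE])
  xm <- x
  dim(xm) <- c(d[1L], prod(d[-1L]))
  out <- xm[idx, , drop = FALSE]
  dim(out) <- c(length(idx), d[-1L])
  out
}
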