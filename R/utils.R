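#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the previous RNG
#' state, so that seeded construction of networks or datasets never perturbs
#' the caller's random stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) pc_stop("pc_numeric_error", "non-finite values in %s", what)
  invisible(x)
}

# coerce a batch to an array with dim c(m, shape); vectors become 1 x n
as_batch <- function(x, shape = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.null(shape)) {
    d <- dim(x)
    if (length(d) != length(shape) + 1L || !all(d[-1L] == shape)) {
      pc_stop("pc_shape_error", "batch has shape (%s), expected (m, %s)",
              paste(dim(x), collapse = ","), paste(shape, collapse = ","))
    }
  }
  x
}

batch_size <- function(x) dim(as_batch(x))[1L]

frob_norm <- function(x) sqrt(sum(unlist(x)^2))

# flatten a (possibly nested) named list of arrays into one numeric vector
flatten_arrays <- function(lst) {
  if (length(lst) == 0L) return(numeric(0))
  as.numeric(unlist(lst, use.names = FALSE))
}

# inverse of flatten_arrays given a skeleton with the same shapes
unflatten_arrays <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  for (i in seq_along(skeleton)) {
    n <- length(skeleton[[i]])
    vals <- vec[pos + seq_len(n)]
    if (is.null(dim(skeleton[[i]]))) out[[i]] <- vals
    else out[[i]] <- array(vals, dim(skeleton[[i]]))
    pos <- pos + n
  }
  stopifnot(pos == length(vec))
  out
}
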