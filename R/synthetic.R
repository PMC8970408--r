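#' Synthetic datasets
#'
#' Seeded, download-free generators producing labeled classification batches
#' with the structure the learning experiments assume: dense inputs, 1-based
#' class labels, and one-hot targets for the squared-Euclidean loss.  Every
#' generator is a pure function of its descriptor: regenerating with the
#' same arguments is bit-identical.
#'
#' A dataset is a `pc_dataset`: a list with `x` (input batch, `(m, ...)`),
#' `labels` (integer vector, 1..K), `y` (one-hot `(m, K)` matrix), and
#' `descriptor` (the generator call, for reproduction and export).
#'
#' @name synthetic_data
NULL

new_dataset <- function(x, labels, K, descriptor) {
  structure(list(x = x, labels = as.integer(labels),
                 y = one_hot(labels, K), K = as.integer(K),
                 descriptor = descriptor),
            class = "pc_dataset")
}

#' @export
print.pc_dataset <- function(x, ...) {
  cat(sprintf("<pc_dataset %s: %d samples, %d classes, input (%s)>\n",
              x$descriptor$kind %||% "?", length(x$labels), x$K,
              paste(dim(x$x)[-1L], collapse = "x")))
  invisible(x)
}

#' One-hot encode class labels
#'
#' Labels are 1-based (R convention): `one_hot(2, 4)` is `c(0, 1, 0, 0)`.
#'
#' @param labels Integer vector with values in `1..K`.
#' @param K Number of classes.
#' @return `length(labels) x K` matrix with a single 1 per row.
#' @export
one_hot <- function(labels, K) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > K)) {
    pc_stop("pc_label_error", "labels must be in 1..%d", K)
  }
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Gaussian blob classification data
#'
#' `K` spherical Gaussian clusters in `dim` dimensions with centers at
#' pairwise distance at least `separation`; labels are the generating
#' cluster, balanced within one sample.
#'
#' @param seed Integer seed.
#' @param n_samples Total number of samples.
#' @param dim Input dimensionality.
#' @param K Number of classes (>= 2).
#' @param separation Minimum pairwise distance between cluster centers.
#' @param noise_sd Within-cluster standard deviation per coordinate.
#' @param centers Optional `K x dim` matrix of cluster centers; pass the
#'   `descriptor$centers` of a training set to draw a held-out split from
#'   the same class structure with fresh noise (use a disjoint seed).
#' @return A `pc_dataset`; the descriptor additionally records the cluster
#'   `centers`.
#' @export
make_blobs <- function(seed, n_samples, dim, K, separation = 6, noise_sd = 1,
                       centers = NULL) {
  stopifnot(K >= 2L, n_samples >= K, dim >= 1L)
  if (!is.null(centers)) stopifnot(all(dim(centers) == c(K, dim)))
  with_seed(seed, {
    # rejection-sample centers until all pairwise distances >= separation
    if (is.null(centers)) repeat {
      centers <- matrix(stats::rnorm(K * dim, sd = separation), K, dim)
      if (K == 1L || min(stats::dist(centers)) >= separation) break
    }
    labels <- rep(seq_len(K), length.out = n_samples)
    x <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * dim, sd = noise_sd), n_samples, dim)
    new_dataset(x, labels, K,
                list(kind = "blobs", seed = seed, n_samples = n_samples,
                     dim = dim, classes = K, separation = separation,
                     noise_sd = noise_sd, centers = centers))
  })
}

#' Teacher-network classification data
#'
#' Labels are the argmax of a frozen random teacher network applied to
#' standard-normal inputs, guaranteeing learnable structure; a fraction
#' `label_noise` of labels is resampled uniformly at random.
#'
#' @param seed Integer seed (also controls the teacher's parameters).
#' @param teacher A `pc_network` whose output width is the class count, or
#'   `NULL` to build a default one-hidden-layer tanh teacher.
#' @param n_samples Number of samples.
#' @param dim Input dimensionality (used only when `teacher` is `NULL`).
#' @param K Number of classes (used only when `teacher` is `NULL`).
#' @param label_noise Fraction of labels resampled uniformly.
#' @return A `pc_dataset`; the descriptor records the teacher.
#' @export
make_teacher_dataset <- function(seed, teacher = NULL, n_samples = 200L,
                                 dim = 8L, K = 4L, label_noise = 0) {
  stopifnot(label_noise >= 0, label_noise <= 1)
  with_seed(seed, {
    if (is.null(teacher)) {
      teacher <- network(list(
        layer_block(list(layer_affine(dim, 16L), layer_tanh(16L))),
        layer_affine(16L, K)))
    }
    dim_in <- teacher$layers[[1L]]$input_shape
    K <- utils::tail(teacher$layers[[teacher$L]]$output_shape, 1L)
    x <- matrix(stats::rnorm(n_samples * prod(dim_in)), n_samples, prod(dim_in))
    if (length(dim_in) > 1L) dim(x) <- c(n_samples, dim_in)
    out <- forward_pass(teacher, x)
    scores <- out[[length(out)]]
    labels <- apply(scores, 1L, which.max)
    flip <- stats::runif(n_samples) < label_noise
    labels[flip] <- sample.int(K, sum(flip), replace = TRUE)
    new_dataset(x, labels, K,
                list(kind = "teacher", seed = seed, n_samples = n_samples,
                     dim = dim_in, classes = K, label_noise = label_noise,
                     teacher = teacher))
  })
}

#' Image-shaped synthetic batches
#'
#' Class-conditional smoothed random textures in `[0, 1]` with shape
#' `(n, channels, height, width)`, for exercising convolutional layers.
#' Each class has a fixed random template; samples are the template plus
#' smoothed pixel noise, squashed to `[0, 1]`.
#'
#' @param seed Integer seed.
#' @param n Number of images.
#' @param channels,height,width Image dimensions.
#' @param K Number of classes.
#' @param noise_sd Pixel noise standard deviation before squashing.
#' @return A `pc_dataset`.
#' @export
make_image_batches <- function(seed, n, channels = 1L, height = 8L, width = 8L,
                               K = 2L, noise_sd = 0.5) {
  stopifnot(n >= 1L, channels >= 1L, height >= 1L, width >= 1L, K >= 1L)
  with_seed(seed, {
    npix <- channels * height * width
    templates <- matrix(stats::rnorm(K * npix), K, npix)
    labels <- rep(seq_len(K), length.out = n)
    raw <- templates[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * npix, sd = noise_sd), n, npix)
    # 3-tap smoothing along the pixel axis, then squash into [0, 1]
    sm <- raw
    if (npix >= 3L) {
      sm[, 2:(npix - 1L)] <- (raw[, 1:(npix - 2L)] + raw[, 2:(npix - 1L)] +
                                raw[, 3:npix]) / 3
    }
    x <- 1 / (1 + exp(-sm))
    dim(x) <- c(n, channels, height, width)
    new_dataset(x, labels, K,
                list(kind = "images", seed = seed, n = n, channels = channels,
                     height = height, width = width, classes = K,
                     noise_sd = noise_sd))
  })
}

#' Export a dataset to plain-text files
#'
#' Writes `x.csv` (samples flattened row-wise), `labels.csv`, and
#' `descriptor.json` into `dir`.
#'
#' @param dataset A `pc_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- dim(dataset$x)[1L]
  xmat <- dataset$x
  dim(xmat) <- c(m, length(xmat) / m)
  utils::write.csv(as.data.frame(xmat), file.path(dir, "x.csv"), row.names = FALSE)
  utils::write.csv(data.frame(label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  desc <- dataset$descriptor
  desc$teacher <- NULL # model objects are not JSON-serializable here
  desc$input_shape <- as.integer(dim(dataset$x)[-1L])
  jsonlite::write_json(desc, file.path(dir, "descriptor.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
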