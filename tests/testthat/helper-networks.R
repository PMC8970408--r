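# fixtures built in code: small seeded networks and batches

sq_loss <- loss_squared_euclidean()
ce_loss <- loss_softmax_cross_entropy()

# the f1(x)=2x, f2(v)=3v scalar chain used by the hand-trace oracles
scalar_chain <- function() {
  network(list(layer_affine(1, 1, W = matrix(2), b = 0),
               layer_affine(1, 1, W = matrix(3), b = 0)))
}

scale_affine <- function(l, scale) {
  l$theta$W <- l$theta$W * scale
  l$theta$b <- l$theta$b * scale
  l
}

# dense net: affine(+activation) blocks, one plain affine output layer
random_dense_net <- function(widths, seed, activation = c("tanh", "relu"),
                             scale = 1) {
  activation <- match.arg(activation)
  act <- if (activation == "tanh") layer_tanh else layer_relu
  L <- length(widths) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    aff <- scale_affine(layer_affine(widths[l], widths[l + 1L],
                                     seed = seed * 100L + l), scale)
    layers[[l]] <- if (l < L) layer_block(list(aff, act(widths[l + 1L]))) else aff
  }
  network(layers)
}

# conv -> flatten-in-block -> dense head; 3 pc layers, all with parameters
random_conv_net <- function(seed, K = 3L) {
  network(list(
    layer_block(list(layer_conv2d(c(1L, 6L, 6L), 2L, 3L, seed = seed * 100L + 1L),
                     layer_relu(c(2L, 4L, 4L)))),
    layer_block(list(layer_flatten(c(2L, 4L, 4L)),
                     layer_affine(32L, 8L, seed = seed * 100L + 2L),
                     layer_tanh(8L))),
    layer_affine(8L, K, seed = seed * 100L + 3L)))
}

random_xy <- function(seed, m, dim_in, K, image = FALSE) {
  with_seed(seed, {
    x <- if (image) array(stats::runif(m * prod(dim_in)), c(m, dim_in))
         else matrix(stats::rnorm(m * dim_in), m, dim_in)
    labels <- sample.int(K, m, replace = TRUE)
    list(x = x, y = one_hot(labels, K), labels = labels)
  })
}

# the 3-layer tanh strict-PC fixture (also the acceptance criterion 4/5 world)
strict_fixture <- function(m = 8L) {
  model <- random_dense_net(c(4L, 6L, 6L, 3L), seed = 77L)
  d <- random_xy(770L, m, 4L, 3L)
  list(model = model, x = d$x, y = d$y)
}

neg <- function(dtheta) lapply(dtheta, function(l) lapply(l, function(a) -a))
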