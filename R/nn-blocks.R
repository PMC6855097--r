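# Dense blocks and residual skip fragments.
#
# A dense block stacks "composite" layers; each composite sees the channel
# concatenation of the block input and every previous composite's output and
# appends `growth` new channels:
#   BN -> ReLU -> 1x1 conv (bottleneck, 4*growth filters)
#      -> BN -> ReLU -> 3x3 conv (growth filters, padding 1).
# A residual skip computes x + f(x) with f two channel-preserving
# conv3x3 -> BN -> ReLU stages, so zero-initialised f is the identity map.

new_composite <- function(c_in, growth, bottleneck_factor = 4L) {
  list(
    bn1 = nn_bn(c_in),
    relu1 = nn_relu(),
    conv1 = nn_conv1(c_in, bottleneck_factor * growth),
    bn2 = nn_bn(bottleneck_factor * growth),
    relu2 = nn_relu(),
    conv3 = nn_conv3(bottleneck_factor * growth, growth)
  )
}

fwd_composite <- function(cl, x, shp, training) {
  h <- fwd_bn(cl$bn1, x, training)
  h <- fwd_relu(cl$relu1, h)
  h <- fwd_conv1(cl$conv1, h)
  h <- fwd_bn(cl$bn2, h, training)
  h <- fwd_relu(cl$relu2, h)
  fwd_conv3(cl$conv3, h, shp)
}

bwd_composite <- function(cl, dy) {
  d <- bwd_conv3(cl$conv3, dy)
  d <- bwd_relu(cl$relu2, d)
  d <- bwd_bn(cl$bn2, d)
  d <- bwd_conv1(cl$conv1, d)
  d <- bwd_relu(cl$relu1, d)
  bwd_bn(cl$bn1, d)
}

#' Build a dense block
#'
#' Constructs a dense block of `n_layers` composite layers with the given
#' growth rate.  The block preserves spatial size and emits
#' `input_channels + n_layers * growth_rate` channels: every composite layer
#' receives the concatenation of the block input and all previous composite
#' outputs, and contributes `growth_rate` new channels.
#'
#' @param input_channels Number of channels entering the block.
#' @param n_layers Number of composite layers (`>= 0`; 0 gives the identity).
#' @param growth_rate Channels added per composite layer.
#' @param bottleneck_factor Width multiplier of the 1x1 bottleneck convolution
#'   relative to the growth rate (default 4).
#' @return A `dense_block` fragment usable inside the network builders; its
#'   `out_channels` field gives the output channel count.
#' @examples
#' blk <- build_dense_block(64, n_layers = 2, growth_rate = 32)
#' blk$out_channels  # 128
#' @export
build_dense_block <- function(input_channels, n_layers, growth_rate,
                              bottleneck_factor = 4L) {
  if (input_channels <= 0) stop("input_channels must be positive")
  if (n_layers < 0) stop("n_layers must be >= 0")
  if (n_layers > 0 && growth_rate <= 0) stop("growth_rate must be positive")
  layers <- lapply(seq_len(n_layers), function(i) {
    new_composite(input_channels + (i - 1L) * growth_rate, growth_rate,
                  bottleneck_factor)
  })
  structure(
    list(kind = "dense_block", c_in = input_channels,
         out_channels = input_channels + n_layers * growth_rate,
         n_layers = n_layers, growth = growth_rate, layers = layers),
    class = "dense_block"
  )
}

fwd_dense_block <- function(blk, x, shp, training) {
  cur <- x
  for (cl in blk$layers) {
    cur <- cbind(cur, fwd_composite(cl, cur, shp, training))
  }
  cur
}

bwd_dense_block <- function(blk, dy) {
  d <- dy
  g <- blk$growth
  for (i in rev(seq_len(blk$n_layers))) {
    w_in <- blk$c_in + (i - 1L) * g
    d_new <- d[, (w_in + 1L):(w_in + g), drop = FALSE]
    d <- d[, seq_len(w_in), drop = FALSE] + bwd_composite(blk$layers[[i]], d_new)
  }
  d
}

#' Build a residual skip fragment
#'
#' Returns a channel- and shape-preserving fragment computing `x + f(x)`,
#' where `f` is two 3x3 convolution + batch-norm + ReLU stages.  Used on the
#' skip paths between encoder and decoder to filter encoder features before
#' they are concatenated into the decoder.  With `f`'s convolution weights at
#' zero the fragment is exactly the identity map.
#'
#' @param channels Channel count of the input (and output) feature map.
#' @return A `residual_skip` fragment.
#' @export
build_residual_skip <- function(channels) {
  if (channels <= 0) stop("channels must be positive")
  structure(
    list(kind = "residual_skip", c_in = channels, out_channels = channels,
         conv_a = nn_conv3(channels, channels), bn_a = nn_bn(channels),
         relu_a = nn_relu(),
         conv_b = nn_conv3(channels, channels), bn_b = nn_bn(channels),
         relu_b = nn_relu()),
    class = "residual_skip"
  )
}

fwd_residual <- function(rs, x, shp, training) {
  f <- fwd_conv3(rs$conv_a, x, shp)
  f <- fwd_bn(rs$bn_a, f, training)
  f <- fwd_relu(rs$relu_a, f)
  f <- fwd_conv3(rs$conv_b, f, shp)
  f <- fwd_bn(rs$bn_b, f, training)
  f <- fwd_relu(rs$relu_b, f)
  x + f
}

bwd_residual <- function(rs, dy) {
  d <- bwd_relu(rs$relu_b, dy)
  d <- bwd_bn(rs$bn_b, d)
  d <- bwd_conv3(rs$conv_b, d)
  d <- bwd_relu(rs$relu_a, d)
  d <- bwd_bn(rs$bn_a, d)
  dy + bwd_conv3(rs$conv_a, d)
}

#' Run a fragment forward (dense block or residual skip)
#'
#' Convenience entry point used by tests and examples: applies a fragment
#' built by [build_dense_block()] or [build_residual_skip()] to a feature-map
#' batch stored as a `(B*H*W) x C` matrix.
#'
#' @param fragment Fragment object.
#' @param x Feature-map matrix, `(B*H*W)` rows, one column per channel.
#' @param shape Integer vector `c(B, H, W)`.
#' @param training Logical; use batch statistics (TRUE) or running statistics
#'   in the batch-norm layers.
#' @return The output feature-map matrix (same number of rows).
#' @export
fragment_forward <- function(fragment, x, shape, training = TRUE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, nrow(x) == prod(shape))
  switch(fragment$kind,
    dense_block = fwd_dense_block(fragment, x, shape, training),
    residual_skip = fwd_residual(fragment, x, shape, training),
    stop("unknown fragment kind: ", fragment$kind)
  )
}

#' Backward pass through a fragment (gradient of a scalar loss)
#'
#' Must be called after [fragment_forward()] on the same fragment; propagates
#' the upstream gradient through the cached forward state and leaves parameter
#' gradients on the fragment's layers.
#'
#' @param fragment Fragment object (after a forward pass).
#' @param dy Gradient with respect to the fragment output.
#' @return Gradient with respect to the fragment input.
#' @export
fragment_backward <- function(fragment, dy) {
  switch(fragment$kind,
    dense_block = bwd_dense_block(fragment, dy),
    residual_skip = bwd_residual(fragment, dy),
    stop("unknown fragment kind: ", fragment$kind)
  )
}
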