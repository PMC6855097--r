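# DenseU-Net: U-Net skeleton with a dense-block encoder, residual-block skip
# connections and a nearest-neighbour-upsampling decoder.
#
# Default geometry (input 256, stem 32, blocks (1,2,2,4,4) at growth
# (32,32,64,64,128)) gives the encoder channel trace 64, 128, 256, 512, 1024
# and the decoder trace 512, 256, 128, 64 -> 2 -> 1 (sigmoid).

#' Specification of a DenseU-Net
#'
#' @param input_size Input image side length in pixels; must be divisible by
#'   16 (four 2x2 poolings).
#' @param stem_channels Filters of the initial 3x3 convolution feeding the
#'   first dense block.
#' @param block_layers Integer vector of composite-layer counts for the five
#'   encoder dense blocks.
#' @param growth Integer vector of growth rates for the five encoder blocks.
#' @return A `dense_unet_spec` object.
#' @export
dense_unet_spec <- function(input_size = 256L, stem_channels = 32L,
                            block_layers = c(1L, 2L, 2L, 4L, 4L),
                            growth = c(32L, 32L, 64L, 64L, 128L)) {
  input_size <- as.integer(input_size)
  if (input_size <= 0 || input_size %% 16L != 0L)
    stop("input_size must be a positive multiple of 16")
  if (length(block_layers) != 5L || length(growth) != 5L)
    stop("block_layers and growth must each have 5 entries")
  if (any(growth <= 0) || stem_channels <= 0)
    stop("growth rates and stem_channels must be positive")
  ch <- as.integer(stem_channels)
  enc_channels <- integer(5L)
  for (i in 1:5) {
    enc_channels[i] <- ch + as.integer(block_layers[i]) * as.integer(growth[i])
    ch <- enc_channels[i]
  }
  structure(
    list(input_size = input_size, stem_channels = as.integer(stem_channels),
         block_layers = as.integer(block_layers), growth = as.integer(growth),
         enc_channels = enc_channels),
    class = "dense_unet_spec"
  )
}

#' Build a DenseU-Net segmentation network
#'
#' Assembles the full network from a [dense_unet_spec()]: an initial 3x3
#' convolution, five dense blocks with 2x2 max pooling between them, a
#' residual skip fragment on each of the four outer encoder levels, and a
#' decoder of (3x3 conv, nearest 2x upsample, skip concatenation) levels
#' followed by two 1x1 convolutions and a sigmoid producing a single-channel
#' probability map at the input resolution.
#'
#' @param spec A [dense_unet_spec()].
#' @param seed Optional integer seed for weight initialisation.
#' @return A `dense_unet` model object.
#' @export
build_dense_unet <- function(spec = dense_unet_spec(), seed = NULL) {
  stopifnot(inherits(spec, "dense_unet_spec"))
  build <- function() {
    ec <- spec$enc_channels
    net <- list(
      spec = spec,
      stem = list(conv = nn_conv3(1L, spec$stem_channels),
                  bn = nn_bn(spec$stem_channels), relu = nn_relu()),
      enc = lapply(1:5, function(i) {
        build_dense_block(if (i == 1L) spec$stem_channels else ec[i - 1L],
                          spec$block_layers[i], spec$growth[i])
      }),
      pools = lapply(1:4, function(i) nn_pool()),
      skips = lapply(1:4, function(i) build_residual_skip(ec[i])),
      ups = lapply(1:4, function(i) nn_upsample()),
      # decoder 3x3 convs, deepest first: Conv1..Conv4 of the channel trace
      dec = list(
        dec_block(ec[5L], ec[4L]),
        dec_block(2L * ec[4L], ec[3L]),
        dec_block(2L * ec[3L], ec[2L]),
        dec_block(2L * ec[2L], ec[1L])
      ),
      conv5 = list(conv = nn_conv1(2L * ec[1L], 2L), bn = nn_bn(2L),
                   relu = nn_relu()),
      conv6 = nn_conv1(2L, 1L),
      sig = nn_sigmoid()
    )
    structure(net, class = "dense_unet")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

dec_block <- function(c_in, c_out) {
  list(conv = nn_conv3(c_in, c_out), bn = nn_bn(c_out), relu = nn_relu())
}

fwd_dec_block <- function(db, x, shp, training) {
  h <- fwd_conv3(db$conv, x, shp)
  h <- fwd_bn(db$bn, h, training)
  fwd_relu(db$relu, h)
}

bwd_dec_block <- function(db, dy) {
  d <- bwd_relu(db$relu, dy)
  d <- bwd_bn(db$bn, d)
  bwd_conv3(db$conv, d)
}

# x: (B*S*S) x 1 matrix of intensities scaled to [0, 1]
forward_dense_unet <- function(net, x, B, training = FALSE) {
  S <- net$spec$input_size
  stopifnot(nrow(x) == B * S * S)
  shp <- list()
  shp[[1]] <- c(B, S, S)
  for (i in 2:5) shp[[i]] <- c(B, shp[[i - 1]][2] %/% 2L, shp[[i - 1]][3] %/% 2L)

  h <- fwd_conv3(net$stem$conv, x, shp[[1]])
  h <- fwd_bn(net$stem$bn, h, training)
  h <- fwd_relu(net$stem$relu, h)

  e <- vector("list", 5L)
  for (i in 1:5) {
    e[[i]] <- fwd_dense_block(net$enc[[i]], h, shp[[i]], training)
    if (i < 5L) h <- fwd_pool(net$pools[[i]], e[[i]], shp[[i]])
  }

  d <- e[[5]]
  for (lev in 4:1) {
    d <- fwd_dec_block(net$dec[[5L - lev]], d, shp[[lev + 1L]], training)
    d <- fwd_upsample(net$ups[[5L - lev]], d, shp[[lev + 1L]])
    sk <- fwd_residual(net$skips[[lev]], e[[lev]], shp[[lev]], training)
    d <- cbind(d, sk)
  }
  h <- fwd_conv1(net$conv5$conv, d)
  h <- fwd_bn(net$conv5$bn, h, training)
  h <- fwd_relu(net$conv5$relu, h)
  h <- fwd_conv1(net$conv6, h)
  fwd_sigmoid(net$sig, h)
}

backward_dense_unet <- function(net, dprob) {
  ec <- net$spec$enc_channels
  d <- bwd_sigmoid(net$sig, dprob)
  d <- bwd_conv1(net$conv6, d)
  d <- bwd_relu(net$conv5$relu, d)
  d <- bwd_bn(net$conv5$bn, d)
  d <- bwd_conv1(net$conv5$conv, d)

  de <- vector("list", 5L)
  for (lev in 1:4) {
    cu <- ec[lev]   # decoder conv output width == residual skip width
    d_up <- d[, seq_len(cu), drop = FALSE]
    d_sk <- d[, cu + seq_len(cu), drop = FALSE]
    de[[lev]] <- bwd_residual(net$skips[[lev]], d_sk)
    d <- bwd_upsample(net$ups[[5L - lev]], d_up)
    d <- bwd_dec_block(net$dec[[5L - lev]], d)
  }
  # d is now the gradient w.r.t. the fifth encoder block's output
  for (i in 5:1) {
    if (i < 5L) d <- de[[i]] + bwd_pool(net$pools[[i]], d)
    d <- bwd_dense_block(net$enc[[i]], d)
  }
  d <- bwd_relu(net$stem$relu, d)
  d <- bwd_bn(net$stem$bn, d)
  bwd_conv3(net$stem$conv, d)
}

#' Segment an image into a binary thyroid mask
#'
#' Runs a (trained) DenseU-Net on a grayscale image and thresholds the
#' probability map.
#'
#' @param network A `dense_unet` model.
#' @param image Integer/numeric matrix with values in `[0, 255]`, of the
#'   network's input size.
#' @param threshold Probability cut for mask membership (default 0.5).
#' @return Binary mask matrix (`0`/`1`) with the image's dimensions.
#' @export
segment <- function(network, image, threshold = 0.5) {
  stopifnot(inherits(network, "dense_unet"))
  S <- network$spec$input_size
  if (!all(dim(image) == c(S, S)))
    stop("image is ", paste(dim(image), collapse = "x"),
         " but the network expects ", S, "x", S)
  x <- matrix(as.double(t(image)) / 255, ncol = 1L)
  p <- forward_dense_unet(network, x, 1L, training = FALSE)
  matrix(as.integer(p >= threshold), S, S, byrow = TRUE)
}

#' @export
print.dense_unet <- function(x, ...) {
  s <- x$spec
  cat("DenseU-Net segmentation network\n")
  cat("  input: ", s$input_size, "x", s$input_size, "x1\n", sep = "")
  cat("  encoder blocks:",
      paste0("(", s$block_layers, ",", s$growth, ")", collapse = " "), "\n")
  cat("  encoder channels:", paste(s$enc_channels, collapse = " -> "), "\n")
  cat("  conv layers:", count_conv_layers(x), "\n")
  invisible(x)
}

#' Count convolutional layers of a model
#'
#' Counts every 1x1 and 3x3 convolution layer in a built network (fully
#' connected and normalisation layers are not counted).
#'
#' @param model A model or fragment object.
#' @return Integer count.
#' @export
count_conv_layers <- function(model) {
  sum(vapply(collect_layers(model),
             function(l) l$kind %in% c("conv1", "conv3"), logical(1)))
}

#' Symbolic forward shape trace of a network
#'
#' Walks the built network level by level and records each named stage's
#' output spatial size and channel count, without running any data through
#' the network.  Used to verify the architecture against its reference layout.
#'
#' @param model A `dense_unet`, `cnn_classifier`, or `cnn_fusion` object.
#' @param input_size Optional input side length (defaults to the model spec).
#' @return A data.frame with columns `stage`, `size`, `channels`.
#' @export
network_trace <- function(model, input_size = NULL) UseMethod("network_trace")

#' @export
network_trace.dense_unet <- function(model, input_size = NULL) {
  s <- model$spec
  S <- if (is.null(input_size)) s$input_size else as.integer(input_size)
  ec <- s$enc_channels
  sizes <- S / c(1, 2, 4, 8, 16)
  rows <- list(data.frame(stage = "input", size = S, channels = 1L))
  for (i in 1:5) {
    rows[[length(rows) + 1L]] <-
      data.frame(stage = sprintf("dense_%d", i), size = sizes[i],
                 channels = ec[i])
    if (i < 5L)
      rows[[length(rows) + 1L]] <-
        data.frame(stage = sprintf("pool_%d", i), size = sizes[i + 1L],
                   channels = ec[i])
  }
  for (lev in 4:1) {
    rows[[length(rows) + 1L]] <-
      data.frame(stage = sprintf("dec_conv%d", 5L - lev), size = sizes[lev + 1L],
                 channels = ec[lev])
    rows[[length(rows) + 1L]] <-
      data.frame(stage = sprintf("up%d", 5L - lev), size = sizes[lev],
                 channels = ec[lev])
  }
  rows[[length(rows) + 1L]] <- data.frame(stage = "conv5", size = S, channels = 2L)
  rows[[length(rows) + 1L]] <- data.frame(stage = "conv6", size = S, channels = 1L)
  do.call(rbind, rows)
}

## ---- checkpoints ------------------------------------------------------------

#' Save model weights to a checkpoint file
#'
#' The checkpoint embeds the model's spec as a fingerprint; loading into a
#' model with a different spec is refused.
#'
#' @param model A model object (`dense_unet`, `cnn_classifier`, `cnn_fusion`).
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(class = class(model), spec = model$spec,
               weights = get_weights(model)), path)
  invisible(path)
}

#' Load checkpoint weights into a compatible model
#'
#' @param model Model object whose spec must match the checkpoint fingerprint.
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return The model, with weights replaced (modified in place).
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(ck$spec, model$spec))
    stop("checkpoint spec fingerprint does not match the model spec")
  set_weights(model, ck$weights)
  model
}
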