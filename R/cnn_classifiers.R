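# Two-stream nodule classifiers.
#
# CNN-1 (deep stream, raw images) and CNN-2 (shallower stream, mask-restricted
# "ROI" images) share a layout: a 3x3 stem convolution, five dense blocks with
# 2x2 max pooling after the first four, global average pooling, and a 2-way
# softmax head.  CNN-F abandons both heads, concatenates the pooled features
# (1024 + 512 at full scale) and adds a single new softmax head.

CLASS_LABELS <- c("benign", "malignant")

#' Specification of a dense-block image classifier
#'
#' @param input_size Input side length in pixels, divisible by 16.
#' @param block_layers Composite-layer counts of the five dense blocks
#'   (deep stream default `c(1,2,4,8,16)`; shallow stream `c(1,2,4,4,4)`).
#' @param growth_rate Channels added per composite layer (default 32).
#' @param stem_channels Filters of the stem convolution (default 32).
#' @return A `classifier_spec` object; `$feature_length` gives the length of
#'   the pooled feature vector and `$n_conv_layers` the convolutional-layer
#'   count `1 + 2 * sum(block_layers)`.
#' @export
classifier_spec <- function(input_size = 256L,
                            block_layers = c(1L, 2L, 4L, 8L, 16L),
                            growth_rate = 32L, stem_channels = 32L) {
  input_size <- as.integer(input_size)
  if (input_size <= 0 || input_size %% 16L != 0L)
    stop("input_size must be a positive multiple of 16")
  if (length(block_layers) != 5L) stop("block_layers must have 5 entries")
  if (growth_rate <= 0) stop("growth_rate must be positive")
  ch <- as.integer(stem_channels)
  enc_channels <- integer(5L)
  for (i in 1:5) {
    enc_channels[i] <- ch + as.integer(block_layers[i]) * as.integer(growth_rate)
    ch <- enc_channels[i]
  }
  structure(
    list(input_size = input_size, stem_channels = as.integer(stem_channels),
         block_layers = as.integer(block_layers),
         growth_rate = as.integer(growth_rate),
         enc_channels = enc_channels,
         feature_length = enc_channels[5L],
         n_conv_layers = 1L + 2L * sum(as.integer(block_layers))),
    class = "classifier_spec"
  )
}

#' @rdname classifier_spec
#' @export
cnn1_spec <- function(input_size = 256L, growth_rate = 32L,
                      block_layers = c(1L, 2L, 4L, 8L, 16L),
                      stem_channels = 32L) {
  classifier_spec(input_size, block_layers, growth_rate, stem_channels)
}

#' @rdname classifier_spec
#' @export
cnn2_spec <- function(input_size = 256L, growth_rate = 32L,
                      block_layers = c(1L, 2L, 4L, 4L, 4L),
                      stem_channels = 32L) {
  classifier_spec(input_size, block_layers, growth_rate, stem_channels)
}

build_classifier_impl <- function(spec, stream) {
  net <- list(
    spec = spec,
    stream = stream,
    stem = list(conv = nn_conv3(1L, spec$stem_channels),
                bn = nn_bn(spec$stem_channels), relu = nn_relu()),
    blocks = lapply(1:5, function(i) {
      build_dense_block(if (i == 1L) spec$stem_channels
                        else spec$enc_channels[i - 1L],
                        spec$block_layers[i], spec$growth_rate)
    }),
    pools = lapply(1:4, function(i) nn_pool()),
    gap = new_layer("gap"),
    fc = nn_fc(spec$feature_length, 2L)
  )
  structure(net, class = "cnn_classifier")
}

#' Build the deep-stream classifier (CNN-1)
#'
#' @param spec A [classifier_spec()] (defaults to [cnn1_spec()]).
#' @param seed Optional integer seed for weight initialisation.
#' @return A `cnn_classifier` model.
#' @export
build_cnn1 <- function(spec = cnn1_spec(), seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(seed)) build_classifier_impl(spec, "cnn1")
  else with_seed(seed, build_classifier_impl(spec, "cnn1"))
}

#' Build the shallow-stream classifier (CNN-2)
#'
#' @inheritParams build_cnn1
#' @export
build_cnn2 <- function(spec = cnn2_spec(), seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(seed)) build_classifier_impl(spec, "cnn2")
  else with_seed(seed, build_classifier_impl(spec, "cnn2"))
}

# x: (B*S*S) x 1 matrix in [0, 1]
forward_classifier <- function(net, x, B, training = FALSE,
                               features_only = FALSE) {
  S <- net$spec$input_size
  stopifnot(nrow(x) == B * S * S)
  shp <- c(B, S, S)
  h <- fwd_conv3(net$stem$conv, x, shp)
  h <- fwd_bn(net$stem$bn, h, training)
  h <- fwd_relu(net$stem$relu, h)
  for (i in 1:5) {
    h <- fwd_dense_block(net$blocks[[i]], h, shp, training)
    if (i < 5L) {
      h <- fwd_pool(net$pools[[i]], h, shp)
      shp <- c(B, shp[2] %/% 2L, shp[3] %/% 2L)
    }
  }
  feat <- fwd_gap(net$gap, h, shp)
  if (features_only) return(feat)
  fwd_fc(net$fc, feat)
}

backward_classifier <- function(net, d, from_features = FALSE) {
  if (!from_features) d <- bwd_fc(net$fc, d)
  d <- bwd_gap(net$gap, d)
  for (i in 5:1) {
    if (i < 5L) d <- bwd_pool(net$pools[[i]], d)
    d <- bwd_dense_block(net$blocks[[i]], d)
  }
  d <- bwd_relu(net$stem$relu, d)
  d <- bwd_bn(net$stem$bn, d)
  bwd_conv3(net$stem$conv, d)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fusion specification for CNN-F
#'
#' @param input_mode `"pair"` (default): the deep stream receives the raw
#'   image and the shallow stream the mask-restricted image, as produced by
#'   the segmentation cascade. `"single"`: one image is fed to both streams.
#' @return A `fusion_spec` object.
#' @export
fusion_spec <- function(input_mode = c("pair", "single")) {
  structure(list(input_mode = match.arg(input_mode)), class = "fusion_spec")
}

#' Fuse two trained streams into CNN-F
#'
#' Both classification heads are discarded; the global-average-pooled
#' features of the two streams are concatenated and a single new 2-way
#' softmax head is added.  The streams are deep-copied, so fine-tuning the
#' fused model does not modify the donor classifiers.
#'
#' @param cnn1 Trained deep-stream `cnn_classifier`.
#' @param cnn2 Trained shallow-stream `cnn_classifier`.
#' @param fusion A [fusion_spec()].
#' @param seed Optional seed for head initialisation.
#' @return A `cnn_fusion` model; `$spec$feature_length` is the concatenated
#'   feature length (1536 at full scale).
#' @export
build_cnnf <- function(cnn1, cnn2, fusion = fusion_spec(), seed = NULL) {
  stopifnot(inherits(cnn1, "cnn_classifier"), inherits(cnn2, "cnn_classifier"))
  if (cnn1$spec$input_size != cnn2$spec$input_size)
    stop("stream input sizes differ: ", cnn1$spec$input_size, " vs ",
         cnn2$spec$input_size)
  feat_len <- cnn1$spec$feature_length + cnn2$spec$feature_length
  strip_head <- function(net) {
    net$fc <- NULL
    net
  }
  mk <- function() {
    structure(
      list(
        spec = list(stream_a = cnn1$spec, stream_b = cnn2$spec,
                    input_mode = fusion$input_mode, feature_length = feat_len),
        stream_a = strip_head(clone_fragment(unclass(cnn1))),
        stream_b = strip_head(clone_fragment(unclass(cnn2))),
        fc = nn_fc(feat_len, 2L)
      ),
      class = "cnn_fusion"
    )
  }
  if (is.null(seed)) mk() else with_seed(seed, mk())
}

forward_cnnf <- function(net, x_raw, x_roi, B, training = FALSE) {
  fa <- forward_classifier(structure(net$stream_a, class = "cnn_classifier"),
                           x_raw, B, training, features_only = TRUE)
  fb <- forward_classifier(structure(net$stream_b, class = "cnn_classifier"),
                           x_roi, B, training, features_only = TRUE)
  net$fc_input_split <- ncol(fa)
  fwd_fc(net$fc, cbind(fa, fb))
}

backward_cnnf <- function(net, dlogits) {
  d <- bwd_fc(net$fc, dlogits)
  na <- net$spec$stream_a$feature_length
  da <- d[, seq_len(na), drop = FALSE]
  db <- d[, (na + 1L):ncol(d), drop = FALSE]
  backward_classifier(structure(net$stream_a, class = "cnn_classifier"),
                      da, from_features = TRUE)
  backward_classifier(structure(net$stream_b, class = "cnn_classifier"),
                      db, from_features = TRUE)
  invisible(NULL)
}

# images -> network input column, probabilities out
classifier_probs <- function(model, images, images_roi = NULL) {
  B <- length(images)
  x <- images_to_input(images)
  logits <- if (inherits(model, "cnn_fusion")) {
    xb <- if (model$spec$input_mode == "pair") {
      if (is.null(images_roi))
        stop("pair input mode needs the mask-restricted images")
      images_to_input(images_roi)
    } else x
    forward_cnnf(model, x, xb, B, training = FALSE)
  } else {
    forward_classifier(model, x, B, training = FALSE)
  }
  p <- softmax_rows(logits)
  colnames(p) <- CLASS_LABELS
  p
}

images_to_input <- function(images) {
  do.call(rbind, lapply(images, function(im) {
    matrix(as.double(t(im)) / 255, ncol = 1L)
  }))
}

#' Predict the nodule class of images
#'
#' @param object A `cnn_classifier` or `cnn_fusion` model.
#' @param images A single image matrix or a list of image matrices with
#'   values in `[0, 255]`, at the model's input size.
#' @param images_roi For a pair-mode `cnn_fusion` model, the matching
#'   mask-restricted images for the shallow stream.
#' @param ... Unused.
#' @return A data.frame with one row per image: `label` (ties broken toward
#'   `"benign"`), `p_benign`, `p_malignant`.
#' @export
predict.cnn_classifier <- function(object, images, ...) {
  if (is.matrix(images)) images <- list(images)
  p <- classifier_probs(object, images)
  data.frame(label = ifelse(p[, 2L] > p[, 1L], "malignant", "benign"),
             p_benign = p[, 1L], p_malignant = p[, 2L],
             stringsAsFactors = FALSE)
}

#' @rdname predict.cnn_classifier
#' @export
predict.cnn_fusion <- function(object, images, images_roi = NULL, ...) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(images_roi)) images_roi <- list(images_roi)
  p <- classifier_probs(object, images, images_roi)
  data.frame(label = ifelse(p[, 2L] > p[, 1L], "malignant", "benign"),
             p_benign = p[, 1L], p_malignant = p[, 2L],
             stringsAsFactors = FALSE)
}

#' @export
print.cnn_classifier <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Dense-block classifier (%s stream)\n",
              if (identical(x$stream, "cnn1")) "deep" else "shallow"))
  cat("  input: ", s$input_size, "x", s$input_size, "x1\n", sep = "")
  cat("  dense blocks:", paste(s$block_layers, collapse = ","),
      " growth", s$growth_rate, "\n")
  cat("  conv layers:", count_conv_layers(x),
      " feature length:", s$feature_length, "\n")
  invisible(x)
}

#' @export
print.cnn_fusion <- function(x, ...) {
  cat("Fused two-stream classifier (CNN-F)\n")
  cat("  input mode:", x$spec$input_mode, "\n")
  cat("  concatenated feature length:", x$spec$feature_length, "\n")
  invisible(x)
}

#' @export
network_trace.cnn_classifier <- function(model, input_size = NULL) {
  s <- model$spec
  S <- if (is.null(input_size)) s$input_size else as.integer(input_size)
  rows <- list(data.frame(stage = "stem_conv", size = S,
                          channels = s$stem_channels))
  size <- S
  for (i in 1:5) {
    rows[[length(rows) + 1L]] <-
      data.frame(stage = sprintf("dense_%d", i), size = size,
                 channels = s$enc_channels[i])
    if (i < 5L) {
      size <- size %/% 2L
      rows[[length(rows) + 1L]] <-
        data.frame(stage = sprintf("maxpool_%d", i), size = size,
                   channels = s$enc_channels[i])
    }
  }
  rows[[length(rows) + 1L]] <-
    data.frame(stage = "gap", size = 1L, channels = s$feature_length)
  rows[[length(rows) + 1L]] <- data.frame(stage = "fc", size = 1L, channels = 2L)
  do.call(rbind, rows)
}
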