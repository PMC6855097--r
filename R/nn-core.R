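# Core layer primitives for the network engine.
#
# A feature map batch is a (B*H*W) x C numeric matrix (see src/nn_kernels.cpp
# for the row layout).  Layers are environments holding parameters, gradients
# and forward caches; composition (dense blocks, residual skips, full
# networks) lives in nn-blocks.R and the architecture files.

new_layer <- function(kind) {
  l <- new.env(parent = emptyenv())
  l$kind <- kind
  l$trainable <- TRUE
  l
}

#' @noRd
nn_conv3 <- function(c_in, c_out) {
  l <- new_layer("conv3")
  l$c_in <- c_in; l$c_out <- c_out
  # He initialisation for ReLU-family activations
  l$W <- matrix(stats::rnorm(9L * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
                9L * c_in, c_out)
  l$b <- numeric(c_out)
  l
}

nn_conv1 <- function(c_in, c_out) {
  l <- new_layer("conv1")
  l$c_in <- c_in; l$c_out <- c_out
  l$W <- matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out)
  l$b <- numeric(c_out)
  l
}

nn_bn <- function(channels, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("bn")
  l$c_in <- channels; l$c_out <- channels
  l$gamma <- rep(1, channels)
  l$beta <- numeric(channels)
  l$running_mean <- numeric(channels)
  l$running_var <- rep(1, channels)
  l$momentum <- momentum; l$eps <- eps
  l
}

nn_relu <- function() new_layer("relu")
nn_sigmoid <- function() new_layer("sigmoid")
nn_pool <- function() new_layer("pool")
nn_upsample <- function() {
  l <- new_layer("upsample")
  l$mode <- "nearest"
  l
}

nn_fc <- function(n_in, n_out) {
  l <- new_layer("fc")
  l$c_in <- n_in; l$c_out <- n_out
  l$W <- matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  l$b <- numeric(n_out)
  l
}

bcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

## ---- forward / backward per layer kind -------------------------------------

fwd_conv3 <- function(l, x, shp) {
  l$x <- x; l$shp <- shp
  .conv3_forward(x, l$W, l$b, shp[1L], shp[2L], shp[3L])
}

bwd_conv3 <- function(l, dy) {
  g <- .conv3_backward(l$x, l$W, dy, l$shp[1L], l$shp[2L], l$shp[3L])
  if (l$trainable) {
    l$dW <- g$dW; l$db <- drop(g$db)
  } else {
    l$dW <- matrix(0, nrow(l$W), ncol(l$W)); l$db <- numeric(length(l$b))
  }
  g$dX
}

fwd_conv1 <- function(l, x) {
  l$x <- x
  y <- x %*% l$W
  y + bcast(l$b, nrow(y))
}

bwd_conv1 <- function(l, dy) {
  if (l$trainable) {
    l$dW <- crossprod(l$x, dy); l$db <- colSums(dy)
  } else {
    l$dW <- matrix(0, nrow(l$W), ncol(l$W)); l$db <- numeric(length(l$b))
  }
  dy %*% t(l$W)
}

fwd_bn <- function(l, x, training) {
  # frozen batch-norm layers run in inference mode even while the rest of
  # the model trains (standard fine-tuning semantics), so their running
  # statistics stay bit-identical across stages that exclude them
  if (training && nrow(x) > 1L && isTRUE(l$trainable)) {
    s <- .bn_col_stats(x)
    m <- drop(s$mean); v <- drop(s$var)
    l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * m
    l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * v
    l$train_mode <- TRUE
  } else {
    m <- l$running_mean; v <- l$running_var
    l$train_mode <- FALSE
  }
  r <- .bn_forward(x, l$gamma, l$beta, m, v, l$eps)
  l$xhat <- r$xhat; l$invstd <- r$invstd
  r$y
}

bwd_bn <- function(l, dy) {
  r <- .bn_backward(dy, l$xhat, l$gamma, l$invstd, isTRUE(l$train_mode))
  if (l$trainable) {
    l$dgamma <- drop(r$dgamma); l$dbeta <- drop(r$dbeta)
  } else {
    l$dgamma <- numeric(length(l$gamma)); l$dbeta <- numeric(length(l$beta))
  }
  r$dX
}

fwd_relu <- function(l, x) {
  l$mask <- x > 0
  x * l$mask
}

bwd_relu <- function(l, dy) dy * l$mask

fwd_sigmoid <- function(l, x) {
  y <- 1 / (1 + exp(-x))
  l$y <- y
  y
}

bwd_sigmoid <- function(l, dy) dy * l$y * (1 - l$y)

fwd_pool <- function(l, x, shp) {
  r <- .maxpool2_forward(x, shp[1L], shp[2L], shp[3L])
  l$idx <- r$idx; l$n_in <- nrow(x)
  r$y
}

bwd_pool <- function(l, dy) .maxpool2_backward(dy, l$idx, l$n_in)

# index map: each output pixel of the 2x-upsampled grid -> source row
upsample_index <- function(B, H, W) {
  y <- rep(0:(2L * H - 1L), each = 2L * W)
  x <- rep(0:(2L * W - 1L), times = 2L * H)
  p <- (y %/% 2L) * W + (x %/% 2L) + 1L
  as.vector(outer(p, (0:(B - 1L)) * H * W, "+"))
}

# nearest-neighbour 2x upsample; the following 3x3 convolution learns the
# interpolation, so no fixed bilinear stencil is needed
fwd_upsample <- function(l, x, shp) {
  key <- paste(shp, collapse = "x")
  if (is.null(l$key) || l$key != key) {
    l$idx_map <- upsample_index(shp[1L], shp[2L], shp[3L])
    l$key <- key
  }
  x[l$idx_map, , drop = FALSE]
}

bwd_upsample <- function(l, dy) {
  unname(rowsum(dy, l$idx_map))
}

fwd_gap <- function(l, x, shp) {
  hw <- shp[2L] * shp[3L]
  grp <- rep(seq_len(shp[1L]), each = hw)
  l$grp <- grp; l$hw <- hw
  unname(rowsum(x, grp)) / hw
}

bwd_gap <- function(l, dy) dy[l$grp, , drop = FALSE] / l$hw

fwd_fc <- function(l, x) {
  l$x <- x
  x %*% l$W + bcast(l$b, nrow(x))
}

bwd_fc <- function(l, dy) {
  if (l$trainable) {
    l$dW <- crossprod(l$x, dy); l$db <- colSums(dy)
  } else {
    l$dW <- matrix(0, nrow(l$W), ncol(l$W)); l$db <- numeric(length(l$b))
  }
  dy %*% t(l$W)
}

## ---- parameter traversal ----------------------------------------------------

param_names <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")

is_layer <- function(x) is.environment(x) && !is.null(x$kind)

#' Collect all layer environments of a network fragment
#' @noRd
collect_layers <- function(x) {
  if (is_layer(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(unclass(x), collect_layers)))
  list()
}

has_params <- function(l) !is.null(l$W) || !is.null(l$gamma)

collect_param_layers <- function(x) Filter(has_params, collect_layers(x))

set_trainable <- function(x, value) {
  for (l in collect_layers(x)) l$trainable <- value
  invisible(x)
}

#' Extract all weights of a network as a plain list (for checkpoints/hashing)
#' @noRd
get_weights <- function(x) {
  lapply(collect_param_layers(x), function(l) {
    w <- list(W = l$W, b = l$b, gamma = l$gamma, beta = l$beta,
              running_mean = l$running_mean, running_var = l$running_var)
    w[!vapply(w, is.null, logical(1))]
  })
}

set_weights <- function(x, weights) {
  layers <- collect_param_layers(x)
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) {
    for (nm in names(weights[[i]])) layers[[i]][[nm]] <- weights[[i]][[nm]]
  }
  invisible(x)
}

# deep copy so fine-tuning a fused model leaves the donor streams untouched
clone_fragment <- function(x) {
  if (is_layer(x)) {
    l <- new.env(parent = emptyenv())
    for (nm in ls(x, all.names = TRUE)) assign(nm, get(nm, envir = x), envir = l)
    return(l)
  }
  if (is.list(x)) {
    out <- lapply(unclass(x), clone_fragment)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

## ---- optimizers -------------------------------------------------------------

#' Adam / SGD-momentum optimizer over a set of layer environments
#'
#' @param layers list of parameterised layer environments.
#' @param method "adam" or "sgd".
#' @param lr learning rate.
#' @param beta1,beta2 Adam first/second-moment decay rates.
#' @param momentum SGD momentum coefficient.
#' @noRd
make_optimizer <- function(layers, method = c("adam", "sgd"), lr = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, momentum = 0.9,
                           eps = 1e-8) {
  method <- match.arg(method)
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list(); st$v <- list()
  step <- function() {
    st$t <- st$t + 1L
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (!isTRUE(l$trainable)) next
      for (pn in names(param_names)) {
        if (is.null(l[[pn]])) next
        g <- l[[param_names[[pn]]]]
        if (is.null(g)) next
        key <- paste0(i, ".", pn)
        if (method == "adam") {
          if (is.null(st$m[[key]])) {
            st$m[[key]] <- g * 0; st$v[[key]] <- g * 0
          }
          st$m[[key]] <- beta1 * st$m[[key]] + (1 - beta1) * g
          st$v[[key]] <- beta2 * st$v[[key]] + (1 - beta2) * g * g
          mhat <- st$m[[key]] / (1 - beta1^st$t)
          vhat <- st$v[[key]] / (1 - beta2^st$t)
          l[[pn]] <- l[[pn]] - lr * mhat / (sqrt(vhat) + eps)
        } else {
          if (is.null(st$m[[key]])) st$m[[key]] <- g * 0
          st$m[[key]] <- momentum * st$m[[key]] + g
          l[[pn]] <- l[[pn]] - lr * st$m[[key]]
        }
      }
    }
    invisible(NULL)
  }
  list(step = step, state = st, method = method, lr = lr)
}

## ---- misc -------------------------------------------------------------------

# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

round_half_up <- function(x) floor(x + 0.5)
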