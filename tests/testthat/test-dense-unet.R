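# DenseU-Net construction: reference channel/size traces, runtime forward
# shapes at reduced size, the zero-residual degeneracy, segmentation
# thresholding, and checkpoint round trips.

ns <- asNamespace("thyronet")

test_that("the full-size spec reproduces the reference encoder and decoder
           traces", {
  spec <- dense_unet_spec()
  expect_equal(spec$enc_channels, c(64L, 128L, 256L, 512L, 1024L))
  net <- build_dense_unet(spec, seed = 1)
  tr <- network_trace(net)
  want <- list(
    c("dense_1", 256, 64), c("pool_1", 128, 64),
    c("dense_2", 128, 128), c("pool_2", 64, 128),
    c("dense_3", 64, 256), c("pool_3", 32, 256),
    c("dense_4", 32, 512), c("pool_4", 16, 512),
    c("dense_5", 16, 1024),
    c("dec_conv1", 16, 512), c("up1", 32, 512),
    c("dec_conv2", 32, 256), c("up2", 64, 256),
    c("dec_conv3", 64, 128), c("up3", 128, 128),
    c("dec_conv4", 128, 64), c("up4", 256, 64),
    c("conv5", 256, 2), c("conv6", 256, 1)
  )
  for (w in want) {
    row <- tr[tr$stage == w[1], ]
    expect_equal(nrow(row), 1L, label = w[1])
    expect_equal(row$size, as.numeric(w[2]), label = paste(w[1], "size"))
    expect_equal(row$channels, as.numeric(w[3]),
                 label = paste(w[1], "channels"))
  }
  expect_error(dense_unet_spec(input_size = 100), "multiple of 16")
})

test_that("runtime forward shapes match the symbolic trace at reduced size", {
  spec <- dense_unet_spec(input_size = 32L, stem_channels = 4L,
                          growth = c(4L, 4L, 8L, 8L, 16L))
  net <- build_dense_unet(spec, seed = 2)
  x <- matrix(runif(2 * 32 * 32), ncol = 1)
  p <- ns$forward_dense_unet(net, x, 2L, training = FALSE)
  expect_equal(dim(p), c(2 * 32 * 32, 1))
  expect_true(all(p > 0 & p < 1))  # sigmoid of finite logits
  # encoder block outputs recorded during the pass have the spec'd widths
  for (i in 1:5) {
    expect_equal(net$enc[[i]]$out_channels, spec$enc_channels[i])
  }
})

test_that("with zero residual weights the network equals a plain
           dense-encoder U-Net", {
  spec <- dense_unet_spec(input_size = 16L, stem_channels = 2L,
                          block_layers = c(1L, 1L, 1L, 1L, 1L),
                          growth = c(2L, 2L, 2L, 2L, 2L))
  net <- build_dense_unet(spec, seed = 3)
  for (rs in net$skips) {
    rs$conv_a$W[] <- 0; rs$conv_a$b[] <- 0
    rs$conv_b$W[] <- 0; rs$conv_b$b[] <- 0
  }
  x <- matrix(runif(16 * 16), ncol = 1)
  got <- ns$forward_dense_unet(net, x, 1L, training = FALSE)

  # manual forward with identity skips, reusing the same layer objects
  S <- 16L
  shp <- list(c(1L, 16L, 16L), c(1L, 8L, 8L), c(1L, 4L, 4L),
              c(1L, 2L, 2L), c(1L, 1L, 1L))
  h <- ns$fwd_conv3(net$stem$conv, x, shp[[1]])
  h <- ns$fwd_bn(net$stem$bn, h, FALSE)
  h <- ns$fwd_relu(net$stem$relu, h)
  e <- vector("list", 5)
  for (i in 1:5) {
    e[[i]] <- ns$fwd_dense_block(net$enc[[i]], h, shp[[i]], FALSE)
    if (i < 5) h <- ns$fwd_pool(net$pools[[i]], e[[i]], shp[[i]])
  }
  d <- e[[5]]
  for (lev in 4:1) {
    d <- ns$fwd_dec_block(net$dec[[5 - lev]], d, shp[[lev + 1]], FALSE)
    d <- ns$fwd_upsample(net$ups[[5 - lev]], d, shp[[lev + 1]])
    d <- cbind(d, e[[lev]])   # raw skip, no residual filtering
  }
  h <- ns$fwd_conv1(net$conv5$conv, d)
  h <- ns$fwd_bn(net$conv5$bn, h, FALSE)
  h <- ns$fwd_relu(net$conv5$relu, h)
  h <- ns$fwd_conv1(net$conv6, h)
  want <- ns$fwd_sigmoid(net$sig, h)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("segment thresholds the probability map into a mask of the input
           size", {
  spec <- dense_unet_spec(input_size = 32L, stem_channels = 2L,
                          block_layers = c(1L, 1L, 1L, 1L, 1L),
                          growth = c(2L, 2L, 2L, 2L, 2L))
  net <- build_dense_unet(spec, seed = 4)
  img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  m0 <- segment(net, img, threshold = 0)    # every pixel passes
  expect_true(all(m0 == 1L))
  m1 <- segment(net, img, threshold = 1.01) # none passes
  expect_true(all(m1 == 0L))
  m <- segment(net, img)
  expect_equal(dim(m), c(32, 32))
  expect_true(all(m %in% c(0L, 1L)))
  expect_error(segment(net, matrix(0, 16, 16)), "expects 32x32")
})

test_that("checkpoints round-trip weights and refuse mismatched specs", {
  dir <- withr::local_tempdir()
  spec <- dense_unet_spec(input_size = 16L, stem_channels = 2L,
                          block_layers = c(1L, 1L, 1L, 1L, 1L),
                          growth = c(2L, 2L, 2L, 2L, 2L))
  a <- build_dense_unet(spec, seed = 5)
  b <- build_dense_unet(spec, seed = 6)
  p <- file.path(dir, "net.rds")
  save_checkpoint(a, p)
  load_checkpoint(b, p)
  x <- matrix(runif(256), ncol = 1)
  expect_identical(ns$forward_dense_unet(a, x, 1L, FALSE),
                   ns$forward_dense_unet(b, x, 1L, FALSE))
  other <- build_dense_unet(dense_unet_spec(input_size = 32L,
                                            stem_channels = 2L,
                                            block_layers = rep(1L, 5),
                                            growth = rep(2L, 5)), seed = 7)
  expect_error(load_checkpoint(other, p), "fingerprint")
  restored <- restore_checkpoint(p)
  expect_identical(ns$forward_dense_unet(restored, x, 1L, FALSE),
                   ns$forward_dense_unet(a, x, 1L, FALSE))
})
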