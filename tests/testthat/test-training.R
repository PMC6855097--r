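# Training protocols: patient-grouped folds, oversampling, augmentation
# geometry, training-loop smoke and determinism contracts, and staged
# fine-tuning freezes.

ns <- asNamespace("thyronet")

test_that("patient folds never split a patient and are balanced", {
  samples <- stub_samples(rep(c("benign", "malignant"), each = 5),
                          images_per_patient = 2L)
  folds <- make_patient_folds(samples, k = 5L, seed = 1)
  expect_length(folds, 10L)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(unname(table(folds)), rep(2L, 5), ignore_attr = TRUE)
  for (f in 1:5) {
    sp <- fold_split(samples, folds, f)
    expect_length(sp$val, 4L)   # 2 patients x 2 images
    expect_length(intersect(unique(ns$sample_patients(sp$train)),
                            unique(ns$sample_patients(sp$val))), 0L)
  }
  expect_identical(folds, make_patient_folds(samples, 5L, seed = 1))
  expect_false(identical(folds, make_patient_folds(samples, 5L, seed = 2)))
  expect_equal(unique(make_patient_folds(samples, 1L, seed = 3)), 1L)
  expect_error(make_patient_folds(samples[1:2], 5L, seed = 1), "at least k")
})

test_that("folds are label-stratified within one patient of an even split", {
  set.seed(42)
  for (i in 1:20) {
    nb <- sample(5:20, 1); nm <- sample(5:20, 1); k <- sample(2:5, 1)
    samples <- stub_samples(c(rep("benign", nb), rep("malignant", nm)))
    folds <- make_patient_folds(samples, k, seed = i)
    sizes <- table(folds)
    expect_lte(max(sizes) - min(sizes), 1L)
    mal <- table(folds[ns$sample_patients(samples)[
      ns$sample_labels(samples) == "malignant"]])
    expect_lte(max(mal) - min(mal), 1L)
  }
})

test_that("oversampling equalises class counts by duplicating the minority", {
  samples <- stub_samples(c(rep("benign", 10), rep("malignant", 4)))
  out <- oversample_minority(samples, seed = 1)
  tab <- table(ns$sample_labels(out))
  expect_equal(unname(tab["benign"]), 10L)
  expect_equal(unname(tab["malignant"]), 10L)
  # originals retained; duplicates are existing minority samples
  expect_identical(out[1:14], samples)
  extra <- out[15:20]
  expect_true(all(ns$sample_labels(extra) == "malignant"))

  balanced <- stub_samples(rep(c("benign", "malignant"), 3))
  expect_identical(oversample_minority(balanced, seed = 1), balanced)

  big <- stub_samples(c(rep("benign", 1421), rep("malignant", 591)))
  tab2 <- table(ns$sample_labels(oversample_minority(big, seed = 2)))
  expect_equal(unname(tab2["benign"]), 1421L)
  expect_equal(unname(tab2["malignant"]), 1421L)

  expect_error(oversample_minority(stub_samples(rep("benign", 3))),
               "both classes")
})

test_that("augmentation is the identity at zero ranges and an involution
           under double flip", {
  s <- tiny_phantoms(1, image_size = 32L)[[1]]
  zero <- augment_config(horizontal_flip_prob = 0, rotation_range = 0,
                         shear_range = 0)
  expect_identical(augment_sample(s, zero), s)
  flip_only <- augment_config(horizontal_flip_prob = 1, rotation_range = 0,
                              shear_range = 0)
  once <- augment_sample(s, flip_only)
  twice <- augment_sample(once, flip_only)
  expect_identical(twice, s)
  expect_false(identical(once$image, s$image))
})

test_that("augmentation transforms image and mask together with bounded
           mask-area drift", {
  s <- tiny_phantoms(1, image_size = 64L)[[1]]
  cfg <- augment_config()
  set.seed(43)
  for (i in 1:100) {
    a <- augment_sample(s, cfg)
    expect_equal(dim(a$image), dim(s$image))
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_true(all(a$image >= 0 & a$image <= 255))
    drift <- abs(sum(a$mask) - sum(s$mask)) / sum(s$mask)
    expect_lt(drift, 0.05)
  }
})

test_that("segmenter training runs, logs Dice, and is seed-reproducible", {
  spec <- dense_unet_spec(input_size = 32L, stem_channels = 2L,
                          block_layers = rep(1L, 5), growth = rep(2L, 5))
  train <- tiny_phantoms(4, image_size = 32L, seed_base = 300L)
  val <- tiny_phantoms(2, image_size = 32L, seed_base = 400L)
  dir <- withr::local_tempdir()
  run <- function() {
    net <- build_dense_unet(spec, seed = 11)
    train_segmenter(net, train, val,
                    optimizer_config("adam", 1e-4, batch_size = 2L,
                                     epochs = 2L),
                    seed = 11,
                    checkpoint_path = file.path(dir, "seg.rds"))$history
  }
  h1 <- run()
  expect_equal(nrow(h1), 2L)
  expect_true(all(is.finite(h1$train_loss)))
  expect_true(all(h1$val_dice >= 0 & h1$val_dice <= 1))
  expect_true(file.exists(file.path(dir, "seg.rds")))
  expect_identical(h1, run())   # fixed seed reproduces the trajectory
  expect_error(train_segmenter(build_dense_unet(spec), list()), "empty")
})

test_that("classifier training reduces loss on a separable toy set and
           needs masks in roi mode", {
  sp <- classifier_spec(32L, rep(1L, 5), 2L, 2L)
  train <- tiny_phantoms(16, image_size = 32L, seed_base = 500L)
  cl <- build_cnn1(sp, seed = 12)
  fit <- train_classifier(cl, train, NULL,
                          optimizer_config("adam", 1e-3, batch_size = 4L,
                                           epochs = 10L),
                          aug = NULL, seed = 12)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  nomask <- lapply(train, function(s) { s$mask <- NULL; s })
  expect_error(train_classifier(build_cnn2(sp, seed = 1), nomask,
                                mode = "roi"),
               "roi mode requires masks")
})

test_that("staged fine-tuning freezes exactly the not-yet-unlocked blocks", {
  sp <- classifier_spec(32L, rep(1L, 5), 2L, 2L)
  train <- tiny_phantoms(8, image_size = 32L, seed_base = 600L)
  cnn1 <- build_cnn1(sp, seed = 13)
  cnn2 <- build_cnn2(sp, seed = 14)
  w1 <- ns$get_weights(list(cnn1$stem, cnn1$blocks))
  w2 <- ns$get_weights(list(cnn2$stem, cnn2$blocks))

  # stage 0 only: no stream parameter may move
  f0 <- fuse_and_finetune(cnn1, cnn2, train,
                          cfg = fuse_config(head_epochs = 1L, n_stages = 0L),
                          aug = NULL, seed = 13)
  expect_identical(ns$get_weights(list(f0$model$stream_a$stem,
                                       f0$model$stream_a$blocks)), w1)
  expect_identical(ns$get_weights(list(f0$model$stream_b$stem,
                                       f0$model$stream_b$blocks)), w2)

  # one unlock stage: block 5 unfreezes first (back-to-front), blocks 1-4
  # and the stem stay bit-identical in both streams
  f1 <- fuse_and_finetune(cnn1, cnn2, train,
                          cfg = fuse_config(head_epochs = 1L,
                                            stage_epochs = 1L, n_stages = 1L),
                          aug = NULL, seed = 13)
  m <- f1$model
  expect_true(m$stream_a$blocks[[5]]$layers[[1]]$conv3$trainable)
  expect_false(m$stream_a$blocks[[4]]$layers[[1]]$conv3$trainable)
  for (st in list(m$stream_a, m$stream_b)) {
    frozen <- ns$get_weights(list(st$stem, st$blocks[1:4]))
    donor <- if (identical(st$stream, "cnn1")) {
      ns$get_weights(list(cnn1$stem, cnn1$blocks[1:4]))
    } else {
      ns$get_weights(list(cnn2$stem, cnn2$blocks[1:4]))
    }
    expect_identical(frozen, donor)
  }
  # the unlocked block did move
  expect_false(identical(
    ns$get_weights(list(m$stream_a$blocks[[5]])),
    ns$get_weights(list(cnn1$blocks[[5]]))))
  # donors themselves are untouched by fine-tuning
  expect_identical(ns$get_weights(list(cnn1$stem, cnn1$blocks)), w1)
})
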