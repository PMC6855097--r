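# Training protocols: patient-grouped folds, minority oversampling,
# geometric augmentation, the segmenter and classifier training loops, and
# staged freeze/unfreeze fine-tuning of the fused classifier.

#' Optimizer configuration
#'
#' @param method `"adam"` or `"sgd"`.
#' @param learning_rate Positive learning rate.  Reference protocol values:
#'   1e-4 for the segmenter (Adam), 1e-3 for the single-stream classifiers
#'   (Adam), 1e-5 for fused-model fine-tuning (SGD).
#' @param beta1,beta2 Adam exponential decay rates of the first/second moment
#'   estimates (defaults 0.9 / 0.999).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size Mini-batch size (segmenter reference protocol: 2).
#' @param epochs Training epochs.
#' @return An `optimizer_config` object.
#' @export
optimizer_config <- function(method = c("adam", "sgd"), learning_rate = 1e-3,
                             beta1 = 0.9, beta2 = 0.999, momentum = 0.9,
                             batch_size = 2L, epochs = 10L) {
  method <- match.arg(method)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(method = method, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "optimizer_config")
}

#' Augmentation configuration
#'
#' Random horizontal flip, rotation and shear, applied identically to image
#' and mask in segmentation mode (bilinear resampling for images, nearest
#' neighbour for masks, which are re-binarised).
#'
#' @param horizontal_flip_prob Probability of a horizontal flip, in `[0, 1]`.
#' @param rotation_range Maximum absolute rotation in degrees.
#' @param shear_range Maximum absolute shear coefficient (dimensionless).
#' @return An `augment_config` object.
#' @export
augment_config <- function(horizontal_flip_prob = 0.5, rotation_range = 10,
                           shear_range = 0.1) {
  if (horizontal_flip_prob < 0 || horizontal_flip_prob > 1)
    stop("horizontal_flip_prob must lie in [0, 1]")
  structure(list(horizontal_flip_prob = horizontal_flip_prob,
                 rotation_range = rotation_range, shear_range = shear_range),
            class = "augment_config")
}

# rotation + shear about the image centre via EBImage's affine warp
affine_warp <- function(m, angle_deg, shear, bilinear = TRUE) {
  if (angle_deg == 0 && shear == 0) return(m)
  th <- angle_deg * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L) %*%
    matrix(c(1, 0, shear, 1), 2L)
  S <- dim(m)
  ctr <- (S + 1) / 2
  # EBImage: output coords = cbind(input, 1) %*% mt
  mt <- rbind(t(A), ctr - as.vector(ctr %*% t(A)))
  out <- EBImage::affine(EBImage::Image(m), mt,
                         filter = if (bilinear) "bilinear" else "none",
                         bg.col = 0)
  as_mat(out)
}

#' Randomly augment one sample
#'
#' Draws a horizontal flip, a rotation and a shear from the configured
#' ranges using the current RNG stream and applies the same geometric
#' transform to the image and (when present) the mask.
#'
#' @param sample A `ct_sample`.
#' @param cfg An [augment_config()].
#' @return The augmented sample; image re-clipped to `[0, 255]`, mask
#'   re-binarised.
#' @export
augment_sample <- function(sample, cfg = augment_config()) {
  flip <- stats::runif(1) < cfg$horizontal_flip_prob
  angle <- if (cfg$rotation_range > 0)
    stats::runif(1, -cfg$rotation_range, cfg$rotation_range) else 0
  shear <- if (cfg$shear_range > 0)
    stats::runif(1, -cfg$shear_range, cfg$shear_range) else 0
  img <- sample$image
  if (flip) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  img <- affine_warp(img, angle, shear, bilinear = TRUE)
  img <- round_half_up(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  sample$image <- img
  if (!is.null(sample$mask)) {
    msk <- sample$mask
    if (flip) msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    msk <- affine_warp(msk, angle, shear, bilinear = FALSE)
    sample$mask <- (msk >= 0.5) * 1L
  }
  sample
}

sample_labels <- function(samples) {
  vapply(samples, function(s) {
    if (is.null(s$label)) NA_character_ else s$label
  }, character(1))
}

sample_patients <- function(samples) {
  vapply(samples, function(s) s$patient_id, character(1))
}

#' Patient-grouped, label-stratified fold assignment
#'
#' Patients are shuffled by seed and dealt to `k` folds so that all images
#' of a patient share a fold, fold sizes differ by at most one patient, and
#' each fold's malignant patient count is within one of an even split.
#'
#' @param samples List of `ct_sample` objects.
#' @param k Number of folds.
#' @param seed Integer RNG seed.
#' @return Named integer vector mapping patient id to fold (1..k).
#' @export
make_patient_folds <- function(samples, k = 5L, seed = 1L) {
  pid <- sample_patients(samples)
  lab <- sample_labels(samples)
  pat <- !duplicated(pid)
  patients <- pid[pat]
  plab <- lab[pat]
  if (length(patients) < k)
    stop("need at least k = ", k, " distinct patients, have ",
         length(patients))
  with_seed(seed, {
    strata <- if (all(is.na(plab))) list(seq_along(patients))
              else split(seq_along(patients), plab)
    ordered <- unlist(lapply(strata, function(ix) ix[sample.int(length(ix))]),
                      use.names = FALSE)
    fold <- ((seq_along(ordered) - 1L) %% k) + 1L
    out <- integer(length(patients))
    out[ordered] <- fold
    names(out) <- patients
    out
  })
}

#' Split samples into train/validation sets of one fold
#'
#' @param samples List of samples.
#' @param folds Assignment from [make_patient_folds()].
#' @param fold Validation fold index.
#' @return List with `train` and `val` sample lists.
#' @export
fold_split <- function(samples, folds, fold) {
  f <- folds[sample_patients(samples)]
  list(train = samples[f != fold], val = samples[f == fold])
}

#' Oversample the minority class to balance training data
#'
#' Minority-class samples are duplicated by sampling with replacement until
#' both class counts are equal.  Apply to the training split only.
#'
#' @param samples List of labelled samples (two classes present).
#' @param seed Integer RNG seed.
#' @return The balanced sample list (originals first, duplicates appended).
#' @export
oversample_minority <- function(samples, seed = 1L) {
  lab <- sample_labels(samples)
  if (anyNA(lab)) stop("all samples must be labelled")
  tab <- table(lab)
  if (length(tab) < 2L) stop("both classes must be present")
  if (tab[1] == tab[2]) return(samples)
  minority <- names(tab)[which.min(tab)]
  deficit <- abs(diff(as.integer(tab)))
  pool <- which(lab == minority)
  with_seed(seed, {
    extra <- pool[sample.int(length(pool), deficit, replace = TRUE)]
    c(samples, samples[extra])
  })
}

## ---- batch assembly ---------------------------------------------------------

seg_batch <- function(samples) {
  x <- images_to_input(lapply(samples, `[[`, "image"))
  t <- do.call(rbind, lapply(samples, function(s) {
    matrix(as.double(t(s$mask)), ncol = 1L)
  }))
  list(x = x, t = t)
}

label_onehot <- function(labels) {
  y <- matrix(0, length(labels), 2L)
  y[cbind(seq_along(labels), ifelse(labels == "malignant", 2L, 1L))] <- 1
  y
}

cls_inputs <- function(samples, mode) {
  imgs <- lapply(samples, function(s) {
    if (mode == "roi") {
      if (is.null(s$mask)) stop("roi mode requires masks on every sample")
      apply_mask(s$image, s$mask)
    } else s$image
  })
  images_to_input(imgs)
}

## ---- segmenter training -----------------------------------------------------

#' Train a DenseU-Net segmenter
#'
#' Reference protocol: Adam with learning rate 1e-4, decay rates 0.9/0.999,
#' Dice loss, batches of two, real-time augmentation, random initial
#' weights.  Per-epoch training loss and validation Dice are logged; when a
#' patience is set, training stops after that many epochs without validation
#' improvement and the best weights are restored.
#'
#' @param network A `dense_unet` model (modified in place).
#' @param train_samples,val_samples Lists of samples with masks.
#' @param opt An [optimizer_config()].
#' @param aug An [augment_config()]; `NULL` disables augmentation.
#' @param seed Integer seed controlling shuffling and augmentation.
#' @param patience Early-stopping patience in epochs (`Inf` to disable).
#' @param checkpoint_path Optional path to write the final checkpoint.
#' @param verbose Print per-epoch progress.
#' @return List with `network` and `history` (data.frame: epoch,
#'   train_loss, train_dice, val_dice).
#' @export
train_segmenter <- function(network, train_samples, val_samples = NULL,
                            opt = optimizer_config("adam", 1e-4,
                                                   batch_size = 2L,
                                                   epochs = 10L),
                            aug = augment_config(), seed = 1L,
                            patience = Inf, checkpoint_path = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(network, "dense_unet"))
  if (!length(train_samples)) stop("empty training set")
  layers <- collect_param_layers(network)
  optim <- make_optimizer(layers, opt$method, opt$learning_rate,
                          opt$beta1, opt$beta2, opt$momentum)
  n <- length(train_samples)
  bs <- opt$batch_size
  hist <- list()
  best <- list(dice = -Inf, weights = NULL, epoch = 0L)
  with_seed(seed, {
    for (ep in seq_len(opt$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = bs)) {
        ix <- ord[start:min(start + bs - 1L, n)]
        batch <- train_samples[ix]
        if (!is.null(aug)) batch <- lapply(batch, augment_sample, cfg = aug)
        b <- seg_batch(batch)
        B <- length(ix)
        p <- forward_dense_unet(network, b$x, B, training = TRUE)
        hw <- nrow(p) / B
        li <- numeric(B); dp <- matrix(0, nrow(p), 1L)
        for (j in seq_len(B)) {
          rows <- ((j - 1L) * hw + 1L):(j * hw)
          li[j] <- dice_loss(p[rows, 1L], b$t[rows, 1L])
          dp[rows, 1L] <- dice_loss_grad(p[rows, 1L], b$t[rows, 1L]) / B
        }
        losses <- c(losses, mean(li))
        backward_dense_unet(network, dp)
        optim$step()
      }
      vd <- if (length(val_samples))
        mean(segmenter_val_dice(network, val_samples)) else NA_real_
      hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                               train_dice = 1 - mean(losses), val_dice = vd)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val Dice %s", ep, mean(losses),
                        ifelse(is.na(vd), "NA", sprintf("%.4f", vd))))
      if (!is.na(vd) && vd > best$dice) {
        best$dice <- vd; best$epoch <- ep
        if (is.finite(patience)) best$weights <- get_weights(network)
      }
      if (is.finite(patience) && !is.na(vd) && ep - best$epoch >= patience)
        break
    }
  })
  if (!is.null(best$weights) && best$dice > -Inf)
    set_weights(network, best$weights)
  if (!is.null(checkpoint_path)) save_checkpoint(network, checkpoint_path)
  list(network = network, history = do.call(rbind, hist))
}

# mean Dice of thresholded predictions against ground truth, in chunks
segmenter_val_dice <- function(network, samples, threshold = 0.5,
                               chunk = 8L) {
  S <- network$spec$input_size
  out <- numeric(length(samples))
  for (start in seq(1L, length(samples), by = chunk)) {
    ix <- start:min(start + chunk - 1L, length(samples))
    b <- seg_batch(samples[ix])
    p <- forward_dense_unet(network, b$x, length(ix), training = FALSE)
    hw <- S * S
    for (j in seq_along(ix)) {
      rows <- ((j - 1L) * hw + 1L):(j * hw)
      pm <- matrix(as.integer(p[rows, 1L] >= threshold), S, S, byrow = TRUE)
      tm <- matrix(as.integer(b$t[rows, 1L]), S, S, byrow = TRUE)
      out[ix[j]] <- dice_coefficient(pm, tm)
    }
  }
  out
}

## ---- classifier training ----------------------------------------------------

#' Train a single-stream classifier
#'
#' Reference protocol: Adam with learning rate 1e-3 (0.9/0.999), multiclass
#' cross-entropy, minority oversampling on the training split, real-time
#' augmentation.  `mode = "raw"` trains on the original images (deep
#' stream); `mode = "roi"` on mask-restricted images (shallow stream).
#'
#' @param classifier A `cnn_classifier` (modified in place).
#' @param train_samples,val_samples Labelled sample lists (`roi` mode
#'   requires masks).
#' @param opt An [optimizer_config()].
#' @param aug An [augment_config()] or `NULL`.
#' @param mode `"raw"` or `"roi"`.
#' @param oversample Balance training classes by oversampling (default TRUE).
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return List with `classifier` and `history` (epoch, train_loss,
#'   val_accuracy).
#' @export
train_classifier <- function(classifier, train_samples, val_samples = NULL,
                             opt = optimizer_config("adam", 1e-3,
                                                    batch_size = 8L,
                                                    epochs = 10L),
                             aug = augment_config(), mode = c("raw", "roi"),
                             oversample = TRUE, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(classifier, "cnn_classifier"))
  mode <- match.arg(mode)
  if (!length(train_samples)) stop("empty training set")
  if (oversample)
    train_samples <- oversample_minority(train_samples, seed = seed)
  layers <- collect_param_layers(classifier)
  optim <- make_optimizer(layers, opt$method, opt$learning_rate,
                          opt$beta1, opt$beta2, opt$momentum)
  n <- length(train_samples)
  bs <- opt$batch_size
  hist <- list()
  with_seed(seed + 1L, {
    for (ep in seq_len(opt$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = bs)) {
        ix <- ord[start:min(start + bs - 1L, n)]
        batch <- train_samples[ix]
        if (!is.null(aug)) batch <- lapply(batch, augment_sample, cfg = aug)
        x <- cls_inputs(batch, mode)
        y <- label_onehot(sample_labels(batch))
        B <- length(ix)
        logits <- forward_classifier(classifier, x, B, training = TRUE)
        p <- softmax_rows(logits)
        losses <- c(losses, cross_entropy(p, y, mean_per_sample = TRUE))
        backward_classifier(classifier, (p - y) / B)
        optim$step()
      }
      va <- if (length(val_samples))
        classifier_accuracy(classifier, val_samples, mode) else NA_real_
      hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                               val_accuracy = va)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val acc %s", ep, mean(losses),
                        ifelse(is.na(va), "NA", sprintf("%.4f", va))))
    }
  })
  list(classifier = classifier, history = do.call(rbind, hist))
}

# malignant-class probabilities of a model over samples, chunked
model_scores <- function(model, samples, mode = "raw", chunk = 16L) {
  out <- numeric(length(samples))
  for (start in seq(1L, length(samples), by = chunk)) {
    ix <- start:min(start + chunk - 1L, length(samples))
    if (inherits(model, "cnn_fusion")) {
      raw <- lapply(samples[ix], `[[`, "image")
      roi <- if (model$spec$input_mode == "pair")
        lapply(samples[ix], function(s) apply_mask(s$image, s$mask))
      else NULL
      p <- classifier_probs(model, raw, roi)
    } else {
      p <- classifier_probs(model, lapply(samples[ix], function(s) {
        if (mode == "roi") apply_mask(s$image, s$mask) else s$image
      }))
    }
    out[ix] <- p[, "malignant"]
  }
  out
}

classifier_accuracy <- function(model, samples, mode = "raw") {
  sc <- model_scores(model, samples, mode)
  truth <- normalize_labels(sample_labels(samples))
  mean(as.integer(sc > 0.5) == truth)
}

## ---- fused-model fine-tuning ------------------------------------------------

#' Staged fine-tuning configuration for the fused classifier
#'
#' @param head_epochs Epochs of stage 0 (streams frozen, new head trained,
#'   Adam at `head_lr`).
#' @param stage_epochs Epochs per unlock stage (SGD at `finetune_lr`).
#' @param n_stages Number of unlock stages (dense blocks unfrozen deepest
#'   first, one per stage in both streams; at most 5).
#' @param head_lr,finetune_lr Learning rates of the two phases.
#' @param momentum SGD momentum for fine-tuning.
#' @param batch_size Mini-batch size.
#' @return A `fuse_config` object.
#' @export
fuse_config <- function(head_epochs = 5L, stage_epochs = 3L, n_stages = 5L,
                        head_lr = 1e-3, finetune_lr = 1e-5, momentum = 0.9,
                        batch_size = 8L) {
  if (n_stages < 0 || n_stages > 5) stop("n_stages must lie in 0..5")
  structure(list(head_epochs = as.integer(head_epochs),
                 stage_epochs = as.integer(stage_epochs),
                 n_stages = as.integer(n_stages), head_lr = head_lr,
                 finetune_lr = finetune_lr, momentum = momentum,
                 batch_size = as.integer(batch_size)),
            class = "fuse_config")
}

cnnf_stream_blocks <- function(model) {
  list(a = model$stream_a$blocks, b = model$stream_b$blocks)
}

train_cnnf_epochs <- function(model, samples, optim, aug, epochs, bs) {
  n <- length(samples)
  losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      ix <- ord[start:min(start + bs - 1L, n)]
      batch <- samples[ix]
      if (!is.null(aug)) batch <- lapply(batch, augment_sample, cfg = aug)
      x_raw <- cls_inputs(batch, "raw")
      x_roi <- if (model$spec$input_mode == "pair") cls_inputs(batch, "roi")
               else x_raw
      y <- label_onehot(sample_labels(batch))
      B <- length(ix)
      logits <- forward_cnnf(model, x_raw, x_roi, B, training = TRUE)
      p <- softmax_rows(logits)
      losses <- c(losses, cross_entropy(p, y, mean_per_sample = TRUE))
      backward_cnnf(model, (p - y) / B)
      optim$step()
    }
  }
  mean(losses)
}

#' Fuse two trained streams and fine-tune in stages
#'
#' Stage 0 freezes every stream convolution and trains only the new softmax
#' head.  Stages 1..n then unfreeze one dense block per stage, deepest
#' first and in both streams simultaneously, fine-tuning with SGD
#' (reference protocol: learning rate 1e-5, momentum 0.9).  Parameters still
#' frozen in a stage are bit-identical before and after it.
#'
#' @param cnn1,cnn2 Trained stream classifiers.
#' @param train_samples Labelled samples (with masks for pair mode).
#' @param cfg A [fuse_config()].
#' @param fusion A [fusion_spec()].
#' @param aug An [augment_config()] or `NULL`.
#' @param oversample Balance classes before training.
#' @param seed Integer seed.
#' @return List with `model` (the `cnn_fusion`) and `history`
#'   (stage, epochs, mean_loss).
#' @export
fuse_and_finetune <- function(cnn1, cnn2, train_samples,
                              cfg = fuse_config(), fusion = fusion_spec(),
                              aug = augment_config(), oversample = TRUE,
                              seed = 1L) {
  model <- build_cnnf(cnn1, cnn2, fusion, seed = seed)
  if (oversample)
    train_samples <- oversample_minority(train_samples, seed = seed)
  set_trainable(model$stream_a, FALSE)
  set_trainable(model$stream_b, FALSE)
  model$fc$trainable <- TRUE
  hist <- list()
  with_seed(seed + 2L, {
    optim <- make_optimizer(collect_param_layers(model), "adam", cfg$head_lr)
    ml <- train_cnnf_epochs(model, train_samples, optim, aug,
                            cfg$head_epochs, cfg$batch_size)
    hist[[1]] <- data.frame(stage = 0L, epochs = cfg$head_epochs,
                            mean_loss = ml)
    for (st in seq_len(cfg$n_stages)) {
      blk <- 6L - st  # deepest block first
      set_trainable(model$stream_a$blocks[[blk]], TRUE)
      set_trainable(model$stream_b$blocks[[blk]], TRUE)
      optim <- make_optimizer(collect_param_layers(model), "sgd",
                              cfg$finetune_lr, momentum = cfg$momentum)
      ml <- train_cnnf_epochs(model, train_samples, optim, aug,
                              cfg$stage_epochs, cfg$batch_size)
      hist[[st + 1L]] <- data.frame(stage = st, epochs = cfg$stage_epochs,
                                    mean_loss = ml)
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

## ---- texture-shape pretraining ----------------------------------------------

#' Generate one textured-shape pretraining scene
#'
#' Random blobs (ellipses with their own intensity and internal Gaussian
#' texture) on a random background; the binary target is whether any blob
#' carries strong texture.  Scenes stand in for a natural-image corpus when
#' pretraining the deep stream: they teach generic, background-invariant
#' texture/edge detectors rather than anything phantom-specific.
#'
#' @param image_size Side length in pixels.
#' @return A `ct_sample` whose label is `"malignant"` for textured scenes
#'   and `"benign"` for smooth ones (reusing the two-class plumbing).
#' @export
generate_textured_scene <- function(image_size = 32L) {
  S <- as.integer(image_size)
  g <- coord_grids(S)
  textured <- stats::runif(1) < 0.5
  img <- matrix(runif1(0, 80), S, S)
  n_blob <- sample(1:4, 1L)
  hot <- if (textured) sample.int(n_blob, 1L) else 0L
  for (k in seq_len(n_blob)) {
    cx <- runif1(0.15, 0.85) * S
    cy <- runif1(0.15, 0.85) * S
    a <- runif1(0.08, 0.3) * S
    b <- runif1(0.08, 0.3) * S
    blob <- in_ellipse(g, cx, cy, a, b)
    sdv <- if (k == hot) runif1(12, 25) else runif1(0, 4)
    img[blob] <- runif1(80, 200) + stats::rnorm(sum(blob), 0, sdv)
  }
  img <- round_half_up(pmin(pmax(img + stats::rnorm(S * S, 0, 3), 0), 255))
  structure(list(image = img, mask = NULL,
                 label = if (textured) "malignant" else "benign",
                 patient_id = "pretrain"),
            class = "ct_sample")
}

#' Pretrain a classifier on auto-generated textured shapes
#'
#' Stands in for natural-image pretraining of the deep stream: the
#' classifier learns background-invariant texture detectors on random
#' scenes before seeing any phantom, which markedly improves how well its
#' features localise to the gland region.
#'
#' @param classifier A `cnn_classifier` (modified in place).
#' @param n_scenes Number of random scenes.
#' @param epochs Pretraining epochs (Adam, learning rate 1e-3).
#' @param seed Integer seed.
#' @return The classifier, invisibly.
#' @export
pretrain_textured_shapes <- function(classifier, n_scenes = 300L,
                                     epochs = 4L, seed = 1L) {
  S <- classifier$spec$input_size
  scenes <- with_seed(seed + 7L, {
    lapply(seq_len(n_scenes), function(i) generate_textured_scene(S))
  })
  train_classifier(classifier, scenes, NULL,
                   opt = optimizer_config("adam", 1e-3, batch_size = 8L,
                                          epochs = epochs),
                   aug = NULL, mode = "raw", oversample = FALSE,
                   seed = seed)
  invisible(classifier)
}
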