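# Reference phantom experiments at desk scale.
#
# These harnesses define the package's reproducible study conditions: a
# width-reduced DenseU-Net recovering phantom masks, the two-stream /
# fused-classifier comparison, and the cover-contrast probe of where the
# deep stream's discriminative information lives.  The acceptance script
# and the test suite both run these functions; the methods vignette
# documents the choice of problem sizes.

seg_spec_reduced <- function(image_size = 64L) {
  dense_unet_spec(image_size, stem_channels = 8L,
                  growth = c(8L, 8L, 16L, 16L, 32L))
}

cls_spec_reduced <- function(stream = c("cnn1", "cnn2"), image_size = 32L) {
  stream <- match.arg(stream)
  if (stream == "cnn1")
    cnn1_spec(image_size, growth_rate = 8L, stem_channels = 8L,
              block_layers = c(1L, 1L, 2L, 2L, 4L))
  else
    cnn2_spec(image_size, growth_rate = 8L, stem_channels = 8L,
              block_layers = c(1L, 1L, 1L, 1L, 1L))
}

phantom_set <- function(config, n, seed_base) {
  lapply(seq_len(n), function(i) {
    lab <- if (i %% 2L == 0L) "malignant" else "benign"
    s <- generate_phantom(config, lab, seed = seed_base + i)
    s$patient_id <- sprintf("S%05d", seed_base + i)
    s
  })
}

#' Segmentation parameter-recovery experiment
#'
#' Trains a width-reduced DenseU-Net (64x64 inputs, growth rates 8/8/16/16/32)
#' on synthetic phantoms with the reference protocol (Adam 1e-4, Dice loss,
#' batches of two, flip/rotation/shear augmentation) and reports the mean
#' Dice coefficient of thresholded predictions on held-out phantoms.
#' Training runs for up to `epochs` epochs with early stopping on the
#' validation Dice.
#'
#' @param seed Integer seed driving phantom generation, initialisation and
#'   training randomness.
#' @param n_train,n_val Phantom counts.
#' @param image_size Input side length (multiple of 16).
#' @param epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param verbose Print per-epoch progress.
#' @return List: `val_dice` (mean held-out Dice), `history`, `network`.
#' @export
segmentation_recovery_experiment <- function(seed = 1L, n_train = 200L,
                                             n_val = 50L, image_size = 64L,
                                             epochs = 30L, patience = 4L,
                                             verbose = FALSE) {
  cfg <- phantom_config(image_size = image_size)
  base <- seed * 1000L
  train <- phantom_set(cfg, n_train, base)
  val <- phantom_set(cfg, n_val, base + n_train + 1000L)
  net <- build_dense_unet(seg_spec_reduced(image_size), seed = seed)
  fit <- train_segmenter(net, train, val,
                         optimizer_config("adam", 1e-4, batch_size = 2L,
                                          epochs = epochs),
                         aug = augment_config(), seed = seed,
                         patience = patience, verbose = verbose)
  list(val_dice = mean(segmenter_val_dice(fit$network, val)),
       history = fit$history, network = fit$network)
}

fusion_cohort <- function(seed, image_size = 32L, n_patients = 100L,
                          images_per_patient = 3L,
                          malignant_fraction = 0.35) {
  cfg <- phantom_config(image_size = image_size)
  generate_cohort(cfg, n_patients, images_per_patient, malignant_fraction,
                  seed = seed + 11L)
}

#' Two-stream fusion experiment
#'
#' On one phantom cohort (patient-grouped train/validation split): trains
#' the reduced deep stream on raw images (with textured-shape pretraining),
#' the reduced shallow stream on mask-restricted images, fuses them with a
#' fresh softmax head, fine-tunes in stages, and reports the validation
#' accuracy of all three models.
#'
#' @param seed Integer seed.
#' @param image_size Input side length.
#' @param epochs Training epochs per stream.
#' @return Named numeric vector `c(cnn1 = ..., cnn2 = ..., cnnf = ...)`.
#' @export
fusion_experiment <- function(seed = 1L, image_size = 32L, epochs = 8L) {
  co <- fusion_cohort(seed, image_size)
  folds <- make_patient_folds(co$samples, 4L, seed = seed + 3L)
  sp <- fold_split(co$samples, folds, 1L)
  opt <- optimizer_config("adam", 1e-3, batch_size = 8L, epochs = epochs)

  cnn1 <- build_cnn1(cls_spec_reduced("cnn1", image_size), seed = seed)
  pretrain_textured_shapes(cnn1, n_scenes = 300L, epochs = 4L, seed = seed)
  train_classifier(cnn1, sp$train, NULL, opt, mode = "raw", seed = seed)

  cnn2 <- build_cnn2(cls_spec_reduced("cnn2", image_size), seed = seed + 1L)
  train_classifier(cnn2, sp$train, NULL, opt, mode = "roi", seed = seed + 1L)

  fused <- fuse_and_finetune(cnn1, cnn2, sp$train,
                             cfg = fuse_config(head_epochs = 4L,
                                               stage_epochs = 2L,
                                               n_stages = 2L),
                             seed = seed)
  truth <- normalize_labels(sample_labels(sp$val))
  acc_f <- mean(as.integer(model_scores(fused$model, sp$val) > 0.5) == truth)
  c(cnn1 = classifier_accuracy(cnn1, sp$val, "raw"),
    cnn2 = classifier_accuracy(cnn2, sp$val, "roi"),
    cnnf = acc_f)
}

#' Cover-contrast experiment
#'
#' Trains the reduced deep stream on raw phantom images (textured-shape
#' pretraining followed by the standard protocol), builds the two
#' cover-contrast validation sets from the held-out fold with ground-truth
#' masks, and reports accuracy on the raw validation images, the
#' mask-restricted set, and the thyroid-removed set.  The two shifted sets
#' are evaluated with adaptive batch-norm statistics (see
#' [evaluate_cover_contrast()]).
#'
#' @param seed Integer seed.
#' @param image_size Input side length.
#' @param epochs Training epochs.
#' @param replicates Independent repetitions (fresh cohort and training
#'   seeds); reported accuracies are means over the replicates, mirroring
#'   how accuracy curves are usually averaged over training runs.
#' @return Named numeric vector `c(raw = ..., roi = ..., removed = ...)` of
#'   mean accuracies.
#' @export
cover_contrast_experiment <- function(seed = 1L, image_size = 32L,
                                      epochs = 12L, replicates = 3L) {
  one <- function(sd) {
    co <- fusion_cohort(sd, image_size)
    folds <- make_patient_folds(co$samples, 4L, seed = sd + 3L)
    sp <- fold_split(co$samples, folds, 1L)
    cnn1 <- build_cnn1(cls_spec_reduced("cnn1", image_size), seed = sd)
    pretrain_textured_shapes(cnn1, n_scenes = 500L, epochs = 6L, seed = sd)
    train_classifier(cnn1, sp$train, NULL,
                     optimizer_config("adam", 1e-3, batch_size = 8L,
                                      epochs = epochs),
                     mode = "raw", seed = sd)
    sets <- cover_contrast(sp$val)
    acc <- evaluate_cover_contrast(cnn1, sets, adaptive_bn = TRUE)
    c(raw = classifier_accuracy(cnn1, sp$val, "raw"), acc)
  }
  runs <- vapply(seq_len(replicates), function(r) one(seed + 101L * (r - 1L)),
                 numeric(3))
  rowMeans(runs)
}
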