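# End-to-end cascade inference and experiment harnesses: segmentation ->
# mask-restricted classification, the cover-contrast experiment, and
# patient-grouped k-fold cross-validation evaluation.

#' Run the full detection cascade on one image
#'
#' Segments the thyroid region, restricts the image to the predicted mask,
#' and classifies the (raw, mask-restricted) pair with the fused model.  An
#' empty predicted mask flags the result as low-confidence instead of
#' silently classifying.
#'
#' @param segmenter Trained `dense_unet`.
#' @param classifier Trained `cnn_fusion` (or single-stream
#'   `cnn_classifier`, which then sees only the raw image).
#' @param image Grayscale image matrix at the models' input size.
#' @param threshold Segmentation probability threshold.
#' @return A `cascade_result` list: `mask`, `label`, `p_benign`,
#'   `p_malignant`, `low_confidence`, `timings` (seconds per stage).
#' @export
cascade_predict <- function(segmenter, classifier, image, threshold = 0.5) {
  t0 <- proc.time()[["elapsed"]]
  mask <- segment(segmenter, image, threshold)
  t1 <- proc.time()[["elapsed"]]
  roi <- apply_mask(image, mask)
  pred <- if (inherits(classifier, "cnn_fusion"))
    predict(classifier, image, roi)
  else predict(classifier, image)
  t2 <- proc.time()[["elapsed"]]
  structure(
    list(mask = mask, label = pred$label[1L],
         p_benign = pred$p_benign[1L], p_malignant = pred$p_malignant[1L],
         low_confidence = sum(mask) == 0L,
         timings = c(segment = t1 - t0, classify = t2 - t1)),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Cascade prediction:", x$label,
      sprintf("(benign %.3f / malignant %.3f)", x$p_benign, x$p_malignant),
      "\n  mask area:", sum(x$mask),
      if (x$low_confidence) " [LOW CONFIDENCE: empty mask]" else "", "\n")
  invisible(x)
}

#' Run the cascade over a list of samples
#'
#' @param segmenter,classifier Trained models.
#' @param samples List of `ct_sample` objects.
#' @param threshold Segmentation threshold.
#' @return Data.frame with one row per input: `patient_id`, `label`
#'   (predicted), `p_benign`, `p_malignant`, `mask_area`, `low_confidence`,
#'   and `truth` when the samples carry labels.
#' @export
cascade_predict_batch <- function(segmenter, classifier, samples,
                                  threshold = 0.5) {
  rows <- lapply(samples, function(s) {
    r <- cascade_predict(segmenter, classifier, s$image, threshold)
    data.frame(patient_id = s$patient_id, label = r$label,
               p_benign = r$p_benign, p_malignant = r$p_malignant,
               mask_area = sum(r$mask), low_confidence = r$low_confidence,
               truth = if (is.null(s$label)) NA_character_ else s$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the cover-contrast validation sets
#'
#' From samples with masks, constructs validation set 1 (mask-restricted
#' "ROI" images) and validation set 2 (images with the thyroid region
#' removed).  For any sample the two derived images sum pixelwise to the
#' original.  Masks default to DenseU-Net predictions when a segmenter is
#' given, otherwise ground truth is used.
#'
#' @param samples Labelled samples with ground-truth masks.
#' @param segmenter Optional trained `dense_unet`; when supplied, predicted
#'   masks replace ground truth.
#' @param threshold Segmentation threshold for predicted masks.
#' @return List with `roi` (set 1) and `removed` (set 2), both sample lists.
#' @export
cover_contrast <- function(samples, segmenter = NULL, threshold = 0.5) {
  masks <- lapply(samples, function(s) {
    if (!is.null(segmenter)) segment(segmenter, s$image, threshold)
    else {
      if (is.null(s$mask)) stop("cover_contrast requires masks")
      s$mask
    }
  })
  swap <- function(fn) {
    lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      s$image <- fn(s$image, masks[[i]])
      s
    })
  }
  list(roi = swap(apply_mask), removed = swap(remove_region))
}

#' Accuracy of a trained classifier on the cover-contrast sets
#'
#' With `adaptive_bn = TRUE` the batch-normalisation statistics are
#' recomputed on each evaluation set (on a throw-away copy of the model)
#' before thresholding, the standard evaluation practice when a classifier
#' is probed on a covariate-shifted domain such as mask-restricted or
#' region-removed images.
#'
#' @param classifier Trained `cnn_classifier` (typically the deep stream
#'   trained on raw images).
#' @param sets Result of [cover_contrast()].
#' @param adaptive_bn Recompute normalisation statistics per evaluation set.
#' @return Named numeric vector `c(roi = ..., removed = ...)`.
#' @export
evaluate_cover_contrast <- function(classifier, sets, adaptive_bn = FALSE) {
  acc <- function(samples) {
    truth <- normalize_labels(sample_labels(samples))
    sc <- if (adaptive_bn) adaptive_bn_scores(classifier, samples)
          else model_scores(classifier, samples)
    mean(as.integer(sc > 0.5) == truth)
  }
  c(roi = acc(sets$roi), removed = acc(sets$removed))
}

# malignant probabilities with batch statistics taken from the evaluation
# set itself; the model copy (and its updated running stats) is discarded
adaptive_bn_scores <- function(model, samples) {
  m2 <- clone_fragment(unclass(model))
  class(m2) <- class(model)
  x <- images_to_input(lapply(samples, `[[`, "image"))
  lg <- forward_classifier(m2, x, length(samples), training = TRUE)
  softmax_rows(lg)[, 2L]
}

#' Patient-grouped k-fold cross-validation of a classifier builder
#'
#' For each fold: trains a model on the remaining folds via `train_fn`,
#' scores the held-out fold via `score_fn`, and derives per-fold metrics.
#' The aggregate pools all held-out predictions (so aggregate accuracy is
#' total correct / total evaluated) and reports AUC as mean (sd) with a
#' fold-wise 95% confidence interval.
#'
#' @param train_fn `function(train_samples, fold_seed)` returning a model.
#' @param score_fn `function(model, samples)` returning malignant-class
#'   probabilities (defaults to [model_scores()] on raw images).
#' @param samples Labelled samples.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and per-fold training.
#' @param out_dir Optional directory for JSON metrics, per-image prediction
#'   CSV and ROC-point CSV exports.
#' @return List: `per_fold` (metrics reports), `aggregate` (pooled metrics
#'   with `auc_mean`, `auc_sd`, `ci_low`, `ci_high`), `predictions`
#'   (data.frame with fold, patient, truth, score).
#' @export
evaluate_cv <- function(train_fn, samples, k = 5L, seed = 1L,
                        score_fn = NULL, out_dir = NULL) {
  if (is.null(score_fn))
    score_fn <- function(model, ss) model_scores(model, ss)
  folds <- make_patient_folds(samples, k, seed)
  preds <- list()
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    sp <- fold_split(samples, folds, f)
    model <- train_fn(sp$train, seed + f)
    sc <- score_fn(model, sp$val)
    truth <- sample_labels(sp$val)
    preds[[f]] <- data.frame(fold = f,
                             patient_id = sample_patients(sp$val),
                             truth = truth, score = sc,
                             stringsAsFactors = FALSE)
    per_fold[[f]] <- evaluate_predictions(sc, truth)
  }
  pr <- do.call(rbind, preds)
  agg <- evaluate_predictions(pr$score, pr$truth)
  fold_aucs <- vapply(per_fold, function(m) m$auc, numeric(1))
  ok <- !is.na(fold_aucs)
  if (sum(ok) >= 2) {
    ci <- auc_confidence_interval(fold_aucs[ok])
    agg$auc_mean <- ci$mean; agg$auc_sd <- ci$sd
    agg$ci_low <- ci$ci_low; agg$ci_high <- ci$ci_high
  }
  res <- list(per_fold = per_fold, aggregate = agg, predictions = pr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pr, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    write_metrics_json(agg, file.path(out_dir, "metrics.json"))
    roc <- roc_auc(pr$score, pr$truth)
    utils::write.csv(roc$curve, file.path(out_dir, "roc_points.csv"),
                     row.names = FALSE)
  }
  res
}
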