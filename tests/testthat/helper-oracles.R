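# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: straightforward loops and closed forms.

# direct 3x3 convolution with zero padding, matching the engine's
# (offset-major, then channel) weight layout
naive_conv3 <- function(x_mat, W, b, H, Wd) {
  C <- ncol(x_mat); K <- ncol(W)
  out <- matrix(0, H * Wd, K)
  for (k in seq_len(K)) {
    for (y in seq_len(H)) {
      for (x in seq_len(Wd)) {
        acc <- b[k]
        for (dy in -1:1) for (dx in -1:1) {
          sy <- y + dy; sx <- x + dx
          if (sy < 1 || sy > H || sx < 1 || sx > Wd) next
          koff <- (dy + 1) * 3 + (dx + 1)
          for (c in seq_len(C)) {
            acc <- acc + x_mat[(sy - 1) * Wd + sx, c] * W[koff * C + c, k]
          }
        }
        out[(y - 1) * Wd + x, k] <- acc
      }
    }
  }
  out
}

# confusion metrics by per-sample recount
recount_metrics <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  list(
    accuracy = (tp + tn) / length(pred),
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) else NA_real_
  )
}

# AUC by explicit enumeration of positive-negative pairs (ties count 1/2)
enumerate_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# soft Dice loss by direct arithmetic
direct_dice_loss <- function(p, t, eps = 1) {
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

# central-difference gradient of a scalar function of a matrix
central_diff <- function(fn, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (fn(x1) - fn(x2)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# tiny labelled sample stubs (no images) for fold/oversampling tests
stub_samples <- function(patient_labels, images_per_patient = 1L) {
  out <- list()
  for (p in seq_along(patient_labels)) {
    for (j in seq_len(images_per_patient)) {
      out[[length(out) + 1L]] <- structure(
        list(image = matrix(0L, 2, 2), mask = NULL,
             label = patient_labels[[p]],
             patient_id = sprintf("P%03d", p)),
        class = "ct_sample")
    }
  }
  out
}

tiny_phantoms <- function(n, image_size = 32L, seed_base = 100L,
                          labels = NULL) {
  cfg <- phantom_config(image_size = image_size)
  lapply(seq_len(n), function(i) {
    lab <- if (is.null(labels)) {
      if (i %% 2 == 0) "malignant" else "benign"
    } else labels[[i]]
    s <- generate_phantom(cfg, lab, seed = seed_base + i)
    s$patient_id <- sprintf("T%04d", i)
    s
  })
}
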