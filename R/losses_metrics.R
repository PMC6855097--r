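# Dice coefficient / Dice loss, multiclass cross-entropy, confusion-matrix
# metrics, ROC/AUC by pair counting, and fold-wise confidence intervals.

#' Dice coefficient between two binary masks
#'
#' Set-overlap similarity `2|A  B| / (|A| + |B|)`.  Equals the F1 score of
#' the pixel-level confusion matrix.  Two empty masks are defined to have
#' Dice 1 (the 0/0 convention).
#'
#' @param a,b Binary matrices (values 0/1) of equal dimensions.
#' @return Fraction in `[0, 1]`.
#' @examples
#' m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1
#' n <- matrix(0, 4, 4); n[1:2, 1:4] <- 1
#' dice_coefficient(m, n)  # 2*2/(2+4) with block counts 4 and 8 -> 2*4/(4+8)
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("mask dimensions differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Smoothed soft Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p + t) + eps)`, the segmentation training
#' objective; differentiable in the probability map `p`.  The smoothing
#' coefficient rescues the empty-mask case (loss 0 when both `p` and `t` are
#' all zero).
#'
#' @param p Probability map, values in `[0, 1]` (matrix or vector).
#' @param t Binary target mask of the same shape.
#' @param epsilon Smoothing coefficient, `>= 0` (default 1).
#' @return Loss value in `[0, 1]`.
#' @export
dice_loss <- function(p, t, epsilon = 1) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (length(p) != length(t)) stop("p and t have different lengths")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (!all(t %in% c(0, 1))) stop("t must be binary (0/1)")
  1 - (2 * sum(p * t) + epsilon) / (sum(p) + sum(t) + epsilon)
}

# gradient of dice_loss w.r.t. p (used by the training loop)
dice_loss_grad <- function(p, t, epsilon = 1) {
  num <- 2 * sum(p * t) + epsilon
  den <- sum(p) + sum(t) + epsilon
  -(2 * t * den - num) / den^2
}

#' Multiclass cross-entropy
#'
#' `-sum_i sum_j truth[i,j] * log(pred[i,j])` with the convention
#' `0 * log 0 = 0`.  A zero predicted probability on a true class yields
#' `Inf` with a warning rather than a silent value.
#'
#' @param predicted Matrix of predicted class probabilities, one row per
#'   sample, rows summing to 1.
#' @param truth Matrix of one-hot true labels, same shape.
#' @param mean_per_sample If `TRUE`, divide the total by the number of rows.
#' @return Loss value (non-negative, possibly `Inf`).
#' @export
cross_entropy <- function(predicted, truth, mean_per_sample = FALSE) {
  predicted <- rbind(predicted); truth <- rbind(truth)
  if (!all(dim(predicted) == dim(truth)))
    stop("predicted and truth have different shapes")
  if (any(abs(rowSums(predicted) - 1) > 1e-6))
    stop("predicted rows must sum to 1")
  active <- truth > 0
  if (any(predicted[active] == 0)) {
    warning("zero predicted probability on a true class: loss is Inf")
    return(Inf)
  }
  total <- -sum(truth[active] * log(predicted[active]))
  if (mean_per_sample) total / nrow(predicted) else total
}

#' Confusion counts
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion-derived classification metrics
#'
#' Computes accuracy, recall (sensitivity), precision, specificity and F1
#' from the four confusion counts.  Ratios with zero denominators are
#' reported as `NA` with a warning, never silently as 0.
#'
#' @param counts A [confusion_counts()] object (or a list with elements
#'   `TP`, `TN`, `FP`, `FN`).
#' @return A `metrics_report` list with fields `accuracy`, `recall`,
#'   `precision`, `specificity`, `f1`, and `n`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  if (n == 0) stop("at least one count must be positive")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  structure(
    list(accuracy = (TP + TN) / n,
         recall = ratio(TP, TP + FN, "recall"),
         precision = ratio(TP, TP + FP, "precision"),
         specificity = ratio(TN, TN + FP, "specificity"),
         f1 = ratio(2 * TP, 2 * TP + FN + FP, "F1"),
         n = n),
    class = "metrics_report"
  )
}

#' ROC curve and AUC by pair counting
#'
#' AUC via the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs where the positive sample scores higher, with
#' ties counted 1/2.  Curve points (FPR, TPR at every threshold) are returned
#' for plotting or export.
#'
#' @param scores Numeric vector of per-sample scores for the positive
#'   (malignant) class.
#' @param labels Vector of 0/1 (or logical, or `"benign"`/`"malignant"`)
#'   true labels; both classes must be present.
#' @return List with `auc` and a data.frame `curve` (`threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- normalize_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels have different lengths")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to compute AUC")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  # Mann-Whitney pair counting via midranks (exact, ties counted 1/2)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(npos)]) - npos * (npos + 1) / 2) / (npos * nneg)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) sum(neg >= t) / nneg, numeric(1)),
    tpr = vapply(th, function(t) sum(pos >= t) / npos, numeric(1))
  )
  list(auc = auc, curve = curve)
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), CLASS_LABELS)
    if (length(bad))
      stop("unknown labels: ", paste(bad, collapse = ", "),
           " (expected benign/malignant)")
    as.integer(labels == "malignant")
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    labels
  }
}

#' Fold-wise AUC confidence interval
#'
#' Default is the normal-approximation interval across cross-validation
#' folds, `mean +/- 1.96 * sd / sqrt(k)`, clipped to `[0, 1]`.  The
#' `"bootstrap"` method instead resamples folds with replacement and takes
#' percentile bounds of the resampled means.
#'
#' @param per_fold_aucs Numeric vector of per-fold AUC values (length >= 2).
#' @param method `"normal"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (bootstrap method only).
#' @param seed RNG seed for the bootstrap.
#' @return List with `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
auc_confidence_interval <- function(per_fold_aucs,
                                    method = c("normal", "bootstrap"),
                                    n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  k <- length(per_fold_aucs)
  if (k < 2) stop("need at least 2 folds")
  m <- mean(per_fold_aucs)
  s <- stats::sd(per_fold_aucs)
  if (method == "normal") {
    half <- 1.96 * s / sqrt(k)
    lo <- m - half; hi <- m + half
  } else {
    means <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        mean(per_fold_aucs[sample.int(k, k, replace = TRUE)])
      }, numeric(1))
    })
    q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  list(mean = m, sd = s, ci_low = max(0, lo), ci_high = min(1, hi))
}

#' Full evaluation report from per-sample predictions
#'
#' Thresholds the malignant probability at 0.5 (ties toward benign),
#' tabulates the confusion counts with malignant as the positive class,
#' and attaches the pair-counting AUC.
#'
#' @param scores Malignant-class probabilities.
#' @param labels True labels (see [roc_auc()] for accepted encodings).
#' @return A `metrics_report` with `auc` and `counts` attached.
#' @export
evaluate_predictions <- function(scores, labels) {
  labels <- normalize_labels(labels)
  pred <- as.integer(scores > 0.5)
  cc <- confusion_counts(TP = sum(pred == 1 & labels == 1),
                         TN = sum(pred == 0 & labels == 0),
                         FP = sum(pred == 1 & labels == 0),
                         FN = sum(pred == 0 & labels == 1))
  rep <- classification_metrics(cc)
  rep$auc <- if (length(unique(labels)) == 2L) roc_auc(scores, labels)$auc
             else NA_real_
  rep$counts <- cc
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  cat("Classification metrics (n =", x$n, ")\n")
  cat("  accuracy:   ", fmt(x$accuracy), "\n")
  cat("  recall:     ", fmt(x$recall), "\n")
  cat("  precision:  ", fmt(x$precision), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  F1:         ", fmt(x$f1), "\n")
  if (!is.null(x$auc)) cat("  AUC:        ", fmt(x$auc), "\n")
  if (!is.null(x$ci_low))
    cat("  95% CI:     [", fmt(x$ci_low), ",", fmt(x$ci_high), "]\n")
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file path.
#' @export
write_metrics_json <- function(report, path) {
  out <- report[!vapply(report, is.list, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
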