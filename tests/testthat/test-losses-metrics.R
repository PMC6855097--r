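# Dice, cross-entropy, confusion metrics, AUC and fold-wise confidence
# intervals, each checked against independent brute-force recomputation.

test_that("dice coefficient matches hand counts and conventions", {
  m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1          # |A| = 4
  n <- matrix(0, 4, 4); n[1:2, 1:4] <- 1          # |B| = 8, overlap 4
  expect_equal(dice_coefficient(m, n), 2 * 4 / (4 + 8))
  expect_equal(dice_coefficient(m, m), 1)
  d <- matrix(0, 4, 4); d[3:4, 3:4] <- 1
  expect_equal(dice_coefficient(m, d), 0)
  expect_equal(dice_coefficient(m * 0, m * 0), 1)  # empty-mask convention
  expect_error(dice_coefficient(m, matrix(0, 3, 3)), "dimensions")
  expect_error(dice_coefficient(m, n * 2), "binary")
})

test_that("dice loss reproduces closed-form toy values and the epsilon
           conventions", {
  expect_equal(dice_loss(rep(1, 4), rep(1, 4), 1), 0)      # 1 - 9/9
  expect_equal(dice_loss(rep(0, 4), rep(0, 4), 1), 0)      # 1 - 1/1
  expect_equal(dice_loss(rep(1, 4), rep(0, 4), 1), 0.8)    # 1 - 1/5
  expect_error(dice_loss(0.5, 1, -1), "epsilon")
  # perfect prediction gives 0 for any epsilon
  t <- rbinom(20, 1, 0.5)
  for (eps in c(0, 0.5, 1, 10)) expect_equal(dice_loss(t, t, eps), 0)
})

test_that("dice loss agrees with brute force on random inputs and with the
           dice coefficient at epsilon zero", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    p <- runif(n); t <- rbinom(n, 1, 0.5)
    eps <- sample(c(0.5, 1, 2), 1)
    expect_equal(dice_loss(p, t, eps), direct_dice_loss(p, t, eps))
  }
  # binary p, eps = 0: 1 - loss equals the set-overlap Dice, which equals
  # the F1 score of the pixel confusion counts
  for (i in 1:20) {
    p <- rbinom(25, 1, 0.5); t <- rbinom(25, 1, 0.5)
    if (sum(p) + sum(t) == 0) next
    dc <- dice_coefficient(matrix(p, 5), matrix(t, 5))
    expect_equal(1 - dice_loss(p, t, 0), dc)
    f1 <- recount_metrics(p, t)$f1
    expect_equal(dc, f1)
  }
})

test_that("dice loss decreases monotonically as p moves toward t", {
  set.seed(32)
  t <- rbinom(16, 1, 0.5)
  p <- runif(16)
  steps <- vapply(seq(0, 1, by = 0.1), function(a) {
    dice_loss(p + a * (t - p), t)
  }, numeric(1))
  expect_true(all(diff(steps) <= 1e-12))
})

test_that("cross entropy reproduces closed forms and flags zero
           probabilities", {
  expect_equal(cross_entropy(diag(2), diag(2)), 0)
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1)),
               log(2))
  expect_equal(cross_entropy(matrix(c(0.8, 0.2), 1), matrix(c(1, 0), 1)),
               -log(0.8))
  # mean-per-sample flag divides by n
  p <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  y <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(cross_entropy(p, y, mean_per_sample = TRUE),
               cross_entropy(p, y) / 2)
  expect_warning(v <- cross_entropy(matrix(c(0, 1), 1), matrix(c(1, 0), 1)),
                 "Inf")
  expect_identical(v, Inf)
})

test_that("confusion metrics match the worked example and a recount oracle", {
  rep <- classification_metrics(confusion_counts(TP = 8, FN = 2, FP = 1,
                                                 TN = 9))
  expect_equal(rep$accuracy, 0.85)
  expect_equal(rep$recall, 0.8)
  expect_equal(rep$precision, 8 / 9, tolerance = 1e-10)
  expect_equal(rep$specificity, 0.9)
  expect_equal(rep$f1, 16 / 19, tolerance = 1e-10)

  perfect <- classification_metrics(confusion_counts(5, 5, 0, 0))
  for (m in c("accuracy", "recall", "precision", "specificity", "f1"))
    expect_equal(perfect[[m]], 1)
  sym <- classification_metrics(confusion_counts(TP = 3, FN = 3, TN = 2,
                                                 FP = 2))
  expect_equal(sym$accuracy, 0.5)

  set.seed(33)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    cc <- confusion_counts(TP = sum(pred & truth), TN = sum(!pred & !truth),
                           FP = sum(pred & !truth), FN = sum(!pred & truth))
    got <- suppressWarnings(classification_metrics(cc))
    want <- recount_metrics(pred, truth)
    for (m in names(want)) expect_equal(got[[m]], want[[m]], label = m)
  }
})

test_that("zero denominators give NA with a warning, never 0", {
  w <- capture_warnings(r <- classification_metrics(confusion_counts(0, 5,
                                                                     0, 0)))
  expect_true(any(grepl("recall", w)))
  expect_true(any(grepl("F1", w)))
  expect_true(is.na(r$recall))
  expect_true(is.na(suppressWarnings(
    classification_metrics(confusion_counts(0, 5, 0, 0)))$precision))
  expect_error(classification_metrics(confusion_counts(0, 0, 0, 0)),
               "positive")
})

test_that("pair-counting AUC matches enumeration, handles ties, and is
           invariant under monotone transforms", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.7, 0.6, 0.2), c(1, 0, 1, 0))$auc, 0.75)
  set.seed(34)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    got <- roc_auc(scores, labels)$auc
    expect_equal(got, enumerate_auc(scores, labels))
    expect_equal(roc_auc(exp(3 * scores) - 1, labels)$auc, got)
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(35)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- runif(n)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
  }
})

test_that("fold-wise confidence interval matches the closed form and clips", {
  ci <- auc_confidence_interval(c(0.9, 1.0))
  expect_equal(ci$mean, 0.95)
  expect_equal(ci$sd, sd(c(0.9, 1.0)))
  expect_equal(ci$ci_low, 0.95 - 1.96 * ci$sd / sqrt(2), tolerance = 1e-10)
  expect_equal(ci$ci_high, 1)  # clipped at 1
  same <- auc_confidence_interval(rep(0.8, 5))
  expect_equal(c(same$ci_low, same$ci_high), c(0.8, 0.8))
  expect_error(auc_confidence_interval(0.9), "folds")
  # bootstrap alternative: bounds bracket the mean and stay inside the
  # resampled range
  b <- auc_confidence_interval(c(0.7, 0.8, 0.9, 0.85, 0.75),
                               method = "bootstrap", seed = 4)
  expect_true(b$ci_low <= b$mean && b$mean <= b$ci_high)
  expect_gte(b$ci_low, 0.7)
  expect_lte(b$ci_high, 0.9)
})

test_that("the normal-approximation interval has roughly nominal coverage", {
  set.seed(36)
  mu <- 0.8; sigma <- 0.05; k <- 5
  hits <- vapply(1:1000, function(i) {
    ci <- auc_confidence_interval(pmin(1, pmax(0, rnorm(k, mu, sigma))))
    ci$ci_low <= mu && mu <= ci$ci_high
  }, logical(1))
  expect_gt(mean(hits), 0.85)
  expect_lt(mean(hits), 0.99)
})
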