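# thyronet

Detection of benign and malignant thyroid nodules in 2D contrast-enhanced
CT slices by a two-stage deep-learning cascade, implemented as a
self-contained R package:

1. **DenseU-Net segmentation** — a U-Net whose encoder is built from dense
   blocks (each composite layer sees the concatenation of all previous
   outputs; BN → ReLU → 1×1 conv (4k) → BN → ReLU → 3×3 conv (k)) and whose
   skip connections are filtered by residual fragments computing
   `x + f(x)`. Trained with the smoothed Dice loss
   `DL = 1 − (2Σ pₙtₙ + ε)/(Σ(pₙ + tₙ) + ε)`, it maps a 256×256 slice to a
   thyroid probability map (encoder channel trace 64→128→256→512→1024,
   decoder 512→256→128→64→2→1 with a sigmoid).
2. **Two-stream fusion classification (CNN-F)** — a deep stream (CNN-1,
   63 convolutional layers) reads the raw image, a shallower stream
   (CNN-2, 31 layers) reads the mask-restricted ROI image; their softmax
   heads are discarded, the global-average-pooled features concatenated
   (1024 + 512 = 1536) and a single softmax head trained, followed by
   staged back-to-front unfreezing (SGD, lr 1e-5, momentum 0.9).

Evaluation follows the confusion-matrix suite
(accuracy = (TP+TN)/(TP+TN+FP+FN), recall, precision, specificity,
F1 = 2TP/(2TP+FN+FP)), pair-counting (Mann–Whitney) AUC, and fold-wise 95%
confidence intervals over patient-grouped cross-validation in which no
patient's images ever straddle a train/validation split.

Because the original hospital CT archive is unavailable, the package
includes a **synthetic phantom generator**: pseudo-CT slices with a
two-lobed gland, a capsule rim, class-conditional nodule texture with
microcalcification speckles, class-conditional gland enlargement and edge
blur, distractor organs, and exact ground-truth masks. Every experiment in
the package is reproducible from a seed. The network engine itself
(convolutions, batch norm, pooling, Adam/SGD, full backward passes) is
implemented in the package with Rcpp/RcppArmadillo kernels and is verified
against finite-difference gradients in the test suite.

Intended users: researchers studying cascade segmentation/classification
designs for small medical-imaging datasets who need a fully inspectable,
dependency-light reference implementation, and teachers of medical image
analysis who want runnable desk-scale experiments.

## Worked example

Generate phantoms, train a width-reduced DenseU-Net for three epochs, and
segment a held-out slice:

```r
library(thyronet)
cfg <- phantom_config(image_size = 64)
sample <- generate_phantom(cfg, label = "malignant", seed = 7)

train <- lapply(1:40, function(i)
  generate_phantom(cfg, if (i %% 2) "benign" else "malignant", seed = i))
val <- lapply(41:50, function(i)
  generate_phantom(cfg, if (i %% 2) "benign" else "malignant", seed = i))

net <- build_dense_unet(
  dense_unet_spec(input_size = 64, stem_channels = 8,
                  growth = c(8, 8, 16, 16, 32)), seed = 1)
fit <- train_segmenter(net, train, val,
                       optimizer_config("adam", 1e-4, batch_size = 2,
                                        epochs = 3),
                       seed = 1, verbose = TRUE)
#> epoch 1: loss 0.7439 val Dice 0.3882
#> epoch 2: loss 0.5802 val Dice 0.7793
#> epoch 3: loss 0.4777 val Dice 0.8227

mask <- segment(fit$network, sample$image)
dice_coefficient(mask, sample$mask)
#> [1] 0.8693182
```

Three epochs on forty 64×64 phantoms already put the held-out Dice above
0.82 (the full experiment below trains on 200 and exceeds 0.95). The
metrics suite works on any scored predictions:

```r
evaluate_predictions(scores = c(0.9, 0.8, 0.3, 0.6, 0.2, 0.1),
                     labels = c(1, 1, 0, 1, 0, 0))
#> Classification metrics (n = 6 )
#>   accuracy:    1.0000
#>   recall:      1.0000
#>   precision:   1.0000
#>   specificity: 1.0000
#>   F1:          1.0000
#>   AUC:         1.0000
```

The classification half follows the same pattern: `build_cnn1()` /
`build_cnn2()` + `train_classifier()` (modes `"raw"` and `"roi"`),
`fuse_and_finetune()` for CNN-F, `cascade_predict()` for end-to-end
inference, and `evaluate_cv()` for patient-grouped cross-validation. A
command-line front end with subcommands `generate`, `train-seg`,
`train-cls`, `fuse`, `predict`, `evaluate` and `cover-contrast` is
installed at `inst/cli/thyronet`.

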