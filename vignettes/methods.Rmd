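---
title: "Cascaded segmentation and two-stream fusion for thyroid nodule CT: models, phantoms, and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded segmentation and two-stream fusion for thyroid nodule CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Benign and malignant thyroid nodules are hard to tell apart on
contrast-enhanced CT: the gland is small, surrounded by complex tissue, and
the discriminative signs (internal texture, edge sharpness, gland
enlargement) are subtle. `thyronet` implements a two-stage cascade for 2D
CT slices:

1. **Segmentation.** A *DenseU-Net* — a U-Net whose encoder convolutions
   are replaced by dense blocks and whose skip connections are filtered by
   residual blocks — produces a per-pixel probability map of the thyroid
   region, trained with the smoothed Dice loss.
2. **Classification.** Two convolutional streams are trained separately:
   a deep stream (CNN-1, 63 convolutional layers) on the raw image, and a
   shallower stream (CNN-2, 31 layers) on the mask-restricted "ROI" image
   produced by stage 1.  Their classification heads are then discarded,
   the global-average-pooled features concatenated (1024 + 512 = 1536 at
   full scale), and a single softmax head is trained on top (CNN-F),
   followed by staged back-to-front unfreezing of the dense blocks.

All networks are built from two fragment types.  A **dense block** with
`n` composite layers and growth rate `k` maps `C` input channels to
`C + n*k`: each composite layer sees the concatenation of the block input
and every previous layer's output and applies
BN → ReLU → 1×1 conv (4k filters) → BN → ReLU → 3×3 conv (k filters).
A **residual skip** computes `x + f(x)` with `f` two channel-preserving
3×3 conv→BN→ReLU stages, so a zero-initialised skip is exactly the
identity.  The encoder channel trace of the full DenseU-Net is
64 → 128 → 256 → 512 → 1024 with blocks (1,2,2,4,4) at growth rates
(32,32,64,64,128) over a 32-channel stem; the decoder mirrors it with
512 → 256 → 128 → 64 channels, then 1×1 convolutions to 2 and 1 channels
and a sigmoid.

The network engine (convolution, batch normalisation, pooling, Adam/SGD,
and the exact backward passes) is implemented in this package with
Rcpp/RcppArmadillo kernels; gradients of every fragment and of both full
architectures are verified against central differences in the test suite.

## Design choices where the layout was open

* **Stem.** The first dense block's 64-channel output is only consistent
  with a 32-channel input, so a 3×3, 32-filter stem convolution precedes
  it (matching the classifier stems).
* **Upsampling** is nearest-neighbour ×2 followed by a learned 3×3
  convolution.  The following convolution subsumes any fixed
  interpolation, so no bilinear stencil or transposed convolution is
  provided.
* **Residual skip content.** The skip fragment uses two conv→BN→ReLU
  stages; whether the reference design normalises inside the skip is not
  specified, and a zero-initialised skip remains the identity either way.
* **Decoder normalisation.** Decoder convolutions get BN + ReLU for
  training stability; dense-block composites use pre-activation BN as
  their definition requires.
* **Shallow-stream depth.** The shallow stream uses dense blocks
  (1,2,4,4,4): the per-block table and the printed total of 31
  convolutional layers (1 + 2·(1+2+4+4+4)) are mutually consistent, and
  are preferred over a conflicting prose remark describing blocks 3–5 as
  two-layer structures.
* **Tie-breaking.** Softmax ties are resolved toward *benign*; a benign
  default is the conservative choice for a screening aid.
* **Empty segmentations.** If the cascade's predicted mask is empty the
  result is flagged low-confidence rather than silently classified.
* **Batch normalisation when frozen.** Frozen layers run in inference
  mode during fine-tuning, so all frozen parameters — including running
  statistics — are bit-identical across stages that exclude them.
* **Fused input mode.** By default CNN-F receives the (raw,
  mask-restricted) image pair produced by the cascade; a single-image
  mode feeding both streams identically is available
  (`fusion_spec("single")`).

## Training protocols

The reference protocol values are defaults throughout: segmenter — Adam,
learning rate 1e-4, decay rates 0.9/0.999, Dice loss (smoothing
coefficient 1), batches of two, random initialisation; streams — Adam,
1e-3, cross-entropy, minority oversampling to exact class balance on the
training split only; fused model — frozen-stream head training, then SGD
(1e-5, momentum 0.9) while dense blocks unfreeze one per stage from
deepest to shallowest in both streams simultaneously (3 epochs per stage
by default; the unlock step size is a choice, as is the head's Adam 1e-3
optimiser — the head is a freshly initialised layer, for which the
fine-tuning rate would be ineffective).  Real-time augmentation draws a
horizontal flip (p = 0.5), rotation (±10°) and shear (±0.1) per sample;
ranges are unstated in the reference protocol and exposed as
configuration.  Masks are transformed with the identical geometry using
nearest-neighbour resampling and re-binarised.

Cross-validation is patient-grouped and label-stratified: patients are
shuffled, stratified by label, and dealt round-robin to folds, so no
patient's images ever straddle a train/validation boundary, fold sizes
differ by at most one patient, and each fold's malignant count is within
one of an even split.

The deep stream can optionally be **pretrained on auto-generated
textured-shape scenes** (random ellipses with or without strong internal
texture on random backgrounds, labelled by texture presence).  This
stands in for natural-image pretraining: it teaches generic,
background-invariant texture detectors before any phantom is seen.  The
experiments below use it for the raw-image stream.

## The phantom generator

The study's hospital CT data are not publicly available, so every
experiment runs on synthetic pseudo-CT phantoms
(`generate_phantom()` / `generate_cohort()`).  A phantom is a 2D
grayscale slice containing:

* a **gland** drawn as two overlapping ellipse lobes joined by an isthmus
  bar, bright (140–160) against a black (air-level) background, filling
  roughly a quarter of a gland-centred crop;
* a **capsule rim**: a thin, dimmer (45–65) fascia-like interface
  straddling the gland boundary, so gland size and shape remain readable
  both inside and outside the ground-truth mask;
* **nodules**: Gaussian-textured discs inside the gland whose texture
  standard deviation is class-conditional (defaults 6 benign / 18
  malignant; the parenchyma carries the same texture at half amplitude),
  with bright **microcalcification speckles** inside malignant nodules —
  the classic high-contrast malignancy sign;
* class-conditional **gland enlargement**: malignant lobe half-axes are
  scaled by 1.15, so gland area scales by its square (≈1.32); kept
  deliberately secondary to the texture cue, mirroring the reported
  ordering in which internal texture carries most of the signal;
* a class-conditional **edge blur** (Gaussian σ = 2.5 px) applied in a
  band around malignant gland boundaries;
* 0–3 organ-like **distractor blobs** (dim, 30–60) outside the mask, and
  additive acquisition noise (σ = 4).

The ground-truth mask is exactly the set of gland pixels; identical seed
and configuration give bit-identical phantoms.  Parameters were fixed
once while designing the generator: several earlier variants (per-image
background-level jitter, a brighter or one-sided rim) either handed the
classifiers a spurious background feature at desk-scale cohort sizes or
made one cue dominate all others, defeating the purpose of a multi-cue
phantom.

What the phantoms deliberately do **not** model: attenuation physics and
Hounsfield calibration, 3D anatomy and partial-volume effects,
contrast-agent dynamics, scanner artefacts, and the long-tailed
morphological variety of real nodules.  Tests passing on phantoms
demonstrate that the implementation learns and localises the cues the
generator encodes — not clinical performance.

## Desk-scale experiments

The full-data results (validation Dice ≈ 0.955; fused accuracy ≈ 95.7%)
cannot be reproduced without the original CT archive, so the package
ships three property-style experiments at reduced scale, run by both the
test suite and `scripts/acceptance.R`:

* **Segmentation recovery** (`segmentation_recovery_experiment`): a
  width-reduced DenseU-Net (64×64 inputs, stem 8, growth 8/8/16/16/32)
  trained on 200 phantoms with the reference protocol for up to 30
  epochs (early stopping with patience 4 on validation Dice) must reach
  mean Dice ≥ 0.85 on 50 held-out phantoms.  Typical runs reach ≈ 0.95
  within five epochs.
* **Fusion non-degradation** (`fusion_experiment`): on a 100-patient ×
  3-image cohort (35% malignant patients — enriched relative to the
  clinical ratio so that minority counts stay workable at this size),
  CNN-F's validation accuracy must stay within two points of the best
  single stream, across three seeds.
* **Cover-contrast** (`cover_contrast_experiment`): the raw-trained deep
  stream is evaluated on mask-restricted images (validation set 1) and
  thyroid-removed images (validation set 2).  Accuracy on set 1 must
  exceed set 2, and set 2 must stay above chance when the enlargement
  cue is enabled — the size/shape information surviving removal via the
  capsule rim and the hole outline.  Both shifted sets are evaluated
  with *adaptive batch-norm statistics* (recomputed on the evaluation
  set on a throw-away model copy), the standard way to probe a
  classifier under covariate shift — with training-domain statistics,
  thirty-odd stacked normalisation layers amplify the shift into
  arbitrary calibration offsets.  Accuracies are averaged over three
  independent replicates, as accuracy curves are usually averaged over
  training runs.

Problem sizes (image sizes 64/32, cohort sizes, epoch counts) are the
package's chosen desk-scale conditions: large enough for stable
statistics, small enough to re-run routinely on a single CPU core.

## Numerical conventions

* Window-level normalisation maps `[center − width/2, center + width/2]`
  linearly to `[0, 255]`, clips outside, and rounds half-up.
* Dice of two empty masks is 1 (0/0 convention); the Dice-loss smoothing
  coefficient defaults to 1 and rescues the all-empty case.
* Cross-entropy uses the `0·log 0 = 0` convention and reports `Inf` with
  a warning when a true class has zero predicted probability.
* Confusion ratios with zero denominators are `NA` with a warning, never
  silently 0.
* AUC is the Mann–Whitney pair-counting statistic (ties ½), which equals
  trapezoidal integration of the ROC curve and is exactly testable by
  enumeration.
* Fold-wise AUC confidence intervals use the normal approximation
  `mean ± 1.96·sd/√k`, clipped to `[0, 1]`; with five folds its true
  coverage is a few points below nominal (the t quantile would be
  wider), which the test suite measures rather than hides.  A more
  elaborate interval was not warranted for a descriptive summary.
* Masks are stored on disk as {0, 255} PNG and thresholded at 128 on
  load; all image I/O is 8-bit grayscale PNG (JPEG accepted on input).

## Known limitations

* The engine is single-threaded CPU code in double precision: faithful
  and verifiable, but not fast — full-scale 256×256 training is possible
  yet slow; the experiments run width-reduced networks.
* Phantom realism is limited to the statistical cues listed above.
* The cover-contrast experiment's conclusions are sensitive to cohort
  size: much smaller cohorts let the streams latch onto sampling noise,
  which is precisely why the experiment fixes 300 images and averages
  replicates.
* No statistical test between methods is implemented; the reference
  analysis mentions a significance threshold without naming a test.
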