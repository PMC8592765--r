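---
title: "Methods: nested U-Net segmentation of dermoscopic lesions"
author: "dermaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested U-Net segmentation of dermoscopic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model family

Dermoscopic melanoma screening needs a binary mask separating lesion
pixels from surrounding skin. `dermaseg` implements encoder–decoder
("transcoder") convolutional networks for this task. The encoder
contracts the image into a five-level feature pyramid; the decoder
expands back to full resolution; skip connections concatenate
same-resolution encoder features into the decoder so that fine boundary
detail survives the bottleneck.

Three decoder wirings are provided. The classic U-Net uses one decoder
node per level. The nested (dense) UNet++ grid inserts intermediate
nodes `X(i,j)`: level `i`, column `j`, where `X(i,0)` are the encoder
taps and `X(i,j)` for `j >= 1` concatenates *all* same-level
predecessors `X(i,0..j-1)` with the 2x-upsampled `X(i+1,j-1)`. The
package's reference decoder is the pruned variant of that grid: the
same-level fan-in is cut to the immediate predecessor `X(i,j-1)` only.
The grid shape and node internals are unchanged, so the pruned network
is a strict sub-network of the dense one — fewer concatenated channels,
strictly fewer parameters, less computation — while keeping the
multi-column refinement that distinguishes UNet++ from U-Net.

Node internals everywhere are `[3x3 conv -> batch norm -> activation]`
twice, followed by spatial (channel) dropout. Upsampling inside the
nested grids is bilinear x2 followed by a 3x3 conv block; the U-Net
decoder uses 2x2 transposed convolutions (bias, no batch norm), the
classic choice for that architecture. 3x3 convolutions carry a bias even
when batch norm is enabled; with this convention the base-width-8
plain U-Net totals exactly 487,289 trainable parameters, a useful
cross-check of the parameter-counting machinery.

### Encoders

* `plain` — double-conv/max-pool trunk with channel doubling from
  `baseWidth` (8 by default: channels 8,16,32,64,128) and taps at
  strides 1,2,4,8,16. This grid matches the classic U-Net layout, where
  the first double convolution sees the full-resolution image.
* `efficientnet_b0` — stem plus sixteen MBConv blocks (1x1 expansion,
  depthwise conv, squeeze-excitation gated on the block input channels,
  linear projection, identity shortcut when shapes allow), swish
  activations, taps at strides 2..32 with channels 16/24/40/112/320.
* `xception` — depthwise-separable residual trunk (entry flow, eight
  middle-flow blocks, exit flow), ReLU activations, taps at strides
  2..32 with channels 64/128/256/728/2048.

When the shallowest tap sits at stride 2 (both backbone encoders), a
final bilinear x2 precedes the 1x1 head so logits always match the
input resolution. Backbone encoders keep their canonical internal
activations; the `activation` option (`relu`, `prelu`, `gelu`, `swish`,
`mish` — an ablation axis) applies to the decoder and the plain encoder.
Stochastic depth is not implemented; squeeze-excitation reduction is a
quarter of the block input channels. Encoder weights can be loaded from
a package checkpoint via `encoderWeights`; nothing is ever downloaded,
and all shipped tests run from random initialisation.

## Loss and metrics

Training minimises `(1 - alpha) * BCE + alpha * DiceLoss` with
`alpha = 0.5` by default. BCE is the canonical mean pixelwise binary
cross-entropy with probabilities clamped at `1e-7`; the Dice loss is the
global soft Dice `1 - (2*sum(p*y) + eps) / (sum(p) + sum(y) + eps)` with
`eps = 1e-6`, computed over all pixels of the raster (of the minibatch,
during training). The Dice term counters the foreground/background
imbalance typical of lesion masks; BCE keeps per-pixel gradients well
scaled early in training. `alpha` is a free mixing weight with no
canonical value; 0.5 weights both terms equally and is the package
default, overridable everywhere.

Evaluation thresholds sigmoid probabilities at 0.5 with *strict*
inequality (ties fall to background), tallies per-image TP/FP/FN/TN and
reports Dice `2TP/(2TP+FP+FN)`, IoU `TP/(TP+FP+FN)` and pixel accuracy.
Dataset summaries are unweighted means over images; pooled-count
variants are reported alongside. Images where both reference and
prediction are empty have no defined overlap metric; they are skipped
with a warning at dataset level and are an error at single-image level.
Note the algebraic identity `Dice = 2*IoU/(1 + IoU)`: Dice can never be
smaller than IoU, so any tabulation showing otherwise cannot have been
produced by these formulas.

## Preprocessing and augmentation

The input chain is: gray-world colour constancy, then geometric/
photometric augmentation (training only), then subtraction of the fixed
ImageNet channel means (123.68, 116.779, 103.939 on the 0–255 scale),
then scaling to unit range. Gray-world rescales each channel by
`mean(channel means) / channel mean`, which removes global colour casts
from varying illumination — a standard dermoscopy step; it requires
strictly positive channel means and clips to [0, 255]. The placement of
mean subtraction after augmentation is a convention: photometric
augmentations are defined on the natural 0–255 scale.

The augmentation family is: random scaling (0.9–1.1), rotation (±30°),
horizontal/vertical flips (p = 0.5), brightness/contrast shifts (±20%),
CLAHE (p = 0.25), HSV shifts (±10 units), and random cropping. All
magnitudes are conventional dermoscopy choices and fully configurable.
Cropping is the one operation also applied to validation images (with a
fixed per-epoch seed, so validation curves remain comparable);
everything else is train-only.

Geometric operations are applied with identical parameters to image and
mask. The mask travels through the geometric chain as a continuous
field, warped by the *same* bilinear interpolator as the image, and is
thresholded at 0.5 once at the end. This deviates from the common
nearest-neighbour-for-masks rule deliberately: sharing the interpolator
makes image and mask exactly consistent under composed warps (a
property the test suite checks by augmenting an image that replicates
its own mask), while still returning a strictly binary mask; for flips,
crops and integer translations it coincides with nearest-neighbour.
Masks read from disk are binarised with the 8-bit rule `value > 127`,
which tolerates anti-aliased or JPEG-fringed boundaries.

## Training protocol

Adam with its standard moments (beta1 0.9, beta2 0.999, eps 1e-8),
learning rate 1e-4, batch size 2, no schedule and no weight decay.
After every epoch the validation loss and metrics are recorded; the
returned checkpoint is the weights of the epoch that optimised the
checkpoint metric (minimum validation loss by default, maximum
validation Dice optionally). This realises early stopping as
retrospective best-epoch selection — training always runs its full
budget, and the best epoch is picked from the trace — rather than
patience-based halting. A non-finite training loss aborts with an error
naming the epoch and batch.

With minibatches of two, the exponential running statistics of batch
norm lag the weights badly: evaluation-mode forwards (which use running
statistics) can show much higher loss than training-mode forwards on
the same images. The training loop therefore re-estimates the running
statistics exactly before each validation pass ("precise BN"): it
forwards a fixed subset of up to 64 training images in training mode
with dropout disabled, accumulating exact batch means and variances,
and replaces the running statistics with their averages. This only
changes how evaluation-mode normalisation constants are obtained; the
optimisation trajectory is untouched.

One seed governs everything: weight initialisation (fan-out-scaled
He-normal for convolutions — the variance-controlling convention of the
EfficientNet/Xception family, which proved markedly more reliable than
fan-in scaling for these deep bottleneck stacks — ones/zeros for batch
norm, zero biases, 0.25 PReLU slopes), shuffling,
dropout masks, augmentation draws and the synthetic generator. The
engine is single-precision and single-threaded deterministic: two runs
with the same seed and configuration produce bitwise-identical
histories and checkpoints on the same machine.

## The synthetic generator

`syntheticConfig()` defines dermoscopy-like image/mask pairs: a
skin-tone background with a linear illumination ramp, low-frequency
texture and Gaussian noise; a star-convex lesion whose radius is an
ellipse modulated by a random low-order harmonic series (amplitude
`boundaryIrregularity`; 0 gives an exact ellipse), filled with a
darkened colour; optional dark arcs emulating hairs drawn on the image
only. The mask is the exact blob indicator, and the blob axes are
calibrated against the measured pixel area so the lesion area fraction
always lands inside `lesionAreaRange`.

Defaults (64x64, area 5–35%, irregularity 0.15, contrast 0.45, hair
probability 0.3, illumination 0.15, noise sd 6) were chosen once as
plausible desk-scale stand-ins for dermoscopic crops. What the
generator does *not* emulate: camera vignetting, gel bubbles, ruler
markings, multi-lesion scenes, colour variegation inside lesions, and
fuzzy lesion borders. Passing the learning tests therefore demonstrates
that the full pipeline — data, preprocessing, model, gradients,
optimisation, checkpointing, metrics — is wired correctly and can fit a
non-trivial segmentation task; it does not certify clinical-grade
accuracy on real dermoscopy, which requires the real datasets and
pretrained encoders.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at sizes chosen for a laptop-class
CPU: the learning experiment trains the reference model (pruned UNet++
over EfficientNet-B0, ~4.9 M parameters) on 200 synthetic 64x64 images
with 20 for validation, 15 epochs, three seeds, and requires mean Dice
of at least 0.90 on 50 held-out images; the overfit-one-batch smoke test
runs 200 Adam steps at lr 1e-2 on a two-image batch and requires a
combined loss below 0.05. Architecture contracts are checked at input
sizes 64–256. Because the 15-epoch experiment compresses the method's
100-epoch protocol about six-fold, it scales the Adam step size to 3e-4;
the package default stays at the protocol value 1e-4. The dominant
residual error at this scale is hair artifacts being picked up as false
positives — the hardest feature the generator produces, and the last one
the model learns to suppress.

## Numerical and design notes

* Inputs must have height and width divisible by 32 (the deepest tap
  stride); `resizePair()` enforces this and is the suggested remedy in
  the error message.
* Soft-Dice smoothing `1e-6`, BCE clamp `1e-7`, batch-norm eps `1e-5`,
  running-stat momentum 0.1.
* Checkpoint-metric ties resolve to the earliest epoch.
* In comparison tables all column maxima are marked as best (ties share
  the mark), with columns ordered Dice, Accuracy, IoU.
* `decoderWidths` are given shallow-to-deep; the fifth entry is
  reserved (the deepest level has no decoder node). The U-Net decoder
  mirrors the plain encoder's channels, the nested decoders use
  `decoderWidths` (16/32/64/128 by default).
* Dataset splits shuffle ids under the seed; validation and test sizes
  are the rounded fractions and the remainder goes to train, so
  fractions like (0.8, 0, 0.2) over 200 ids give exactly 160/0/40.
* Published parameter totals for backbone nested-decoder networks are
  not comparable across implementations: the decoder is architecturally
  underdetermined (width schedule, upsampling operator, normalisation
  and bias placement each move the total by millions). The package pins
  its reference configuration explicitly (widths 16/32/64/128,
  bilinear+conv upsampling, batch norm on, biased convolutions) and
  verifies the one configuration that *is* canonical — the classic
  base-8 U-Net at 487,289 parameters — exactly.

## Known limitations

No multi-class masks, no DICOM ingest, no hair-removal filtering, no
distributed or mixed-precision training, no learning-rate schedules,
and no photorealistic synthesis. The engine favours determinism and
simplicity over speed; it is fast enough for the desk-scale experiments
shipped here, not for full-resolution clinical datasets.
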