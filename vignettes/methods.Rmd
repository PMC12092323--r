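---
title: "Detecting chromogenic RNAscope dots: models, data generation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromogenic RNAscope dots: models, data generation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnascopeseg)
```

## The problem

RNAscope is an RNA in-situ hybridization assay that renders each detected
transcript as a single visible dot. With the chromogenic (DAB, brown)
detection chemistry on a haematoxylin counterstain, slides can be read on
ordinary bright-field scanners, and the number of dots per cell measures
gene expression. The hard cases are tissues with *weak* staining: the
positive class is extremely rare (a handful of 5-10 px dots in a 480x480
patch), dots vary in hue from pale yellow to dark brown, and annotated
ground truth is scarce and itself noisy — two trained experts agree with
each other only moderately when matched dot-by-dot.

`rnascopeseg` implements a full pipeline for this problem: a synthetic
patch generator with exactly known dot coordinates, a convolutional
segmentation network designed for small and heavily imbalanced datasets, a
phased training curriculum, watershed post-processing that reduces
segmentation maps to dot coordinates, and a tolerance-based F1 evaluator.

## The segmentation network

The network is an encoder-decoder. The encoder ("backbone") is a
ConvNeXt-style stack: a 4x4 stride-4 stem convolution followed by four
stages of residual blocks (7x7 depthwise convolution, layer normalization
over channels, 4x pointwise expansion with GELU, pointwise projection,
per-channel layer scale, DropPath on the branch). The reference size
(`backbone_size = "base"`) uses stage depths 3/3/27/3 and widths
128/256/512/1024; a `"tiny"` preset (depths 2/2/4/2, widths 32/64/128/256)
is provided for CPU-scale experiments and is used throughout the test
suite — it is an engineering reduction, not a published configuration.

The decoder applies the nested U-Net++ wiring, but only *below* the 4x
stem: the four backbone endpoints (1/4 … 1/32 resolution) form the
diagonal of a triangular node grid, and each interior node receives every
same-level predecessor plus the 2x-upsampled node below, concatenated,
projected back to the level width with a pointwise convolution, and passed
through one *custom upscaling block*. That block modifies the ConvNeXt
block for convergence under heavy regularization: layer normalization is
replaced by batch normalization, a second batch normalization guards the
skip path, DropOut (feature-wise, rate `r`) replaces DropPath (which would
skip the only block in front of each upsample and destabilize training),
and an activation closes the block. Upsampling is by 2x2 stride-2
transpose convolution everywhere.

Because the nest tops out at 1/4 resolution, a final section restores full
resolution: twice over, a stride-2 transpose convolution followed by three
ConvNeXt blocks, then a pointwise projection and sigmoid to a 1-channel
map in [0, 1]. Channel widths in this section halve at each upsample
(floored at 8); the widths are not pinned by the design, and halving keeps
the full-resolution stages affordable. The output bias is initialized to
-4 so the network starts out predicting a rare positive class rather than
a 50% map, which stabilizes the first epochs under overlap losses.
Regularization of the final section is selectable (`none`, `dropout`,
`droppath`); `none` is the default.

Design points that were genuinely open, and what this package does:

* **Decoder node widths** are the backbone width of the node's level,
  reached by a 1x1 projection of the concatenated inputs — this bounds
  parameter growth the way standard U-Net++ implementations do.
* **Decoder upsampling operator** is the transpose convolution (only the
  final section's operator is fixed by the design); one operator is used
  consistently.
* **Normalization details**: batch-norm epsilon 1e-5 with momentum 0.9
  running statistics (a faster decay than the framework-default 0.99, so
  inference statistics track training statistics within desk-scale epoch
  counts — with slowly decaying running statistics, a network can predict
  well in training mode while its inference-mode maps lag far behind);
  layer-norm epsilon 1e-6. When the backbone is frozen its normalization
  layers also stop updating (and use) batch statistics, so a frozen
  backbone is bit-stable.
* **DropPath** uses per-sample stochastic depth with rates scaled linearly
  across backbone depth up to the configured `d`, the convention ConvNeXt
  inherits.

The network is implemented on a compact tensor engine written for this
package (channels-first double-precision arrays, C++ kernels for the
dense/depthwise/transpose convolutions and GELU, analytic backward passes
for every layer). The test suite verifies each layer and the whole model
against numerical differentiation.

## Losses and training

Ground truth is rendered as a 5-pixel cross (centre plus 4-neighbours) at
each dot coordinate — inflating each dot slightly eases the extreme class
imbalance. Images are normalized with the ImageNet channel statistics
(images are kept in BGR order, so the statistics are applied reversed).

The package provides binary cross-entropy, Dice, Jaccard and Tversky
losses with *soft* (probabilistic) counts and a smoothing constant
`s = 1e-6` in both numerator and denominator:

\[ L_{Tversky} = 1 - \frac{TP + s}{TP + \alpha FN + \beta FP + s},
   \qquad \beta = 1 - \alpha . \]

Dice is exactly Tversky at \(\alpha = \beta = 0.5\); Jaccard replaces
\(\alpha FN + \beta FP\) with \(FN + FP\) and therefore never scores below
Dice. \(\alpha > 0.5\) weights recall, which suits rare positives; the
default is \(\alpha = 0.6\).

The reference optimizer is AdaDelta with \(\rho = 0.975\), update scale
0.005, epsilon 1e-7, batch size 4 — settings tuned for the multi-thousand-
epoch full-scale curriculum. AdaDelta's squared-update accumulator starts
at zero, so its effective step size warms up over hundreds of batches;
over a few dozen desk-scale epochs the loss barely moves. The trainer
therefore also offers Adam (`optimizer_config("adam")`, defaults 1e-3,
0.9/0.999), which the desk-scale tests use; AdaDelta remains the default
and the full-scale configuration. The reference curriculum
(`default_schedule()`) runs six phases at 460 real samples per epoch (115
patches sampled 4x each) with the per-epoch generated-sample count
halving from 1071 to 0 (128 epochs per phase, 1024 in the last) and the
backbone frozen only in phase 1 — frozen early training protects
pretrained backbone weights, when present, from gradients produced by the
still-random decoder. Pretrained backbone weights can be injected with
`load_backbone_weights()` but are never required; absent weights leave the
random initialization in place with a notice.

Augmentation applies one random rotation (up to 90 degrees, bilinear for
the image, nearest-neighbour for the mask so it stays binary, zero
padding) and independent horizontal/vertical flips to image and mask
jointly. Large patches are subdivided: random 224x224 crops during
training, and a deterministic stride-128 grid at evaluation (which covers
480x480 with a 3x3 grid exactly); tile predictions are stitched by
per-pixel maximum, which favours recall for the rare positive class.
Validation IoU is computed at probability threshold 0.5 and is distinct
from the post-processing grey threshold.

## Post-processing

The raw map is binarized at a configurable 8-bit *grey threshold* (strict
`>`, so grey 254 keeps only saturated pixels) and the watershed transform
over the distance map splits touching clusters; each cluster whose pixel
count reaches the *area threshold* (inclusive, 0 keeps everything)
contributes its rounded centroid as one dot. Watershed details are not
pinned by the design beyond the transform itself; this package adopts the
standard binary-splitting construction (distance-map maxima as markers,
8-connectivity) as implemented by EBImage, and the suite checks it against
a flood-fill component oracle on disjoint blobs and on bridge-joined
dumbbells. A stricter fixed variant used when harvesting natural dots for
data generation first applies a 5x5 circular Gaussian blur and thresholds
at 148 with area threshold 0 — deliberately conservative so few false
positives enter generated training data. `threshold_surface()` sweeps the
(grey, area) grid and reports the F1 argmax with ties broken toward the
smaller area, then the smaller grey threshold.

## Synthetic patches

The generator emulates the data the real pipeline consumes. Each patch
gets a *plan*: a dot count \(n = \mathrm{round}(2^{1+5r})\) (an
exponential scale from 2 to 64 — patches tend to have either few dots or
many); a colour window covering a random contiguous 20% of the linear
light-yellow (225, 253, 255) to dark-brown (160, 200, 217) BGR axis (dots
within one patch resemble each other); a 25% chance that the patch carries
dark-centred secondary dots at all, and if so a per-dot secondary
probability drawn from 0-50%.

Each dot is a *subtractive* BGR mask: one centre pixel set to
`255 - colour`, blurred with a 9x9 circular Gaussian, then rescaled so the
centre regains its pre-blur value. Secondary dots add a second mask built
the same way with fixed colour (200, 210, 215) and a 5x5 kernel — at
least 40 of darkening per channel — at a random offset of up to one pixel,
reproducing the off-centre yellow tinge of dark dots. The mask is then
perturbed: each cardinal half-axis stretched by 0-3 px, anisotropic
scaling by \(0.25\text{-}0.5 + 0.4r^2\) per axis (the shared squared term
makes substantially larger dots rare), multiplicative per-pixel noise in
0.975-1.025, and rotation by a random integer angle. Dots are placed
uniformly, redrawn until at least 3 px from every other dot (with a
1000-attempt budget per dot so crowded patches fail loudly instead of
looping forever), and subtracted from the background with clipping at 0;
coordinates are recorded exactly.

Choices the published construction leaves open, fixed here once:

* **Blur kernel**: Gaussian with \(\sigma = \text{size}/4\), zeroed
  outside the inscribed circle, normalized; matches common
  "circular kernel" practice.
* **Post-blur rescale** is a single scalar per channel chosen so the
  centre regains its pre-blur value (the minimal reading of "multiplied").
* **Cardinal stretch** resamples the four half-axis regions bilinearly to
  the stretched radial length, with support clamped so the stretched
  extent is exact.
* **Noise** is drawn independently per pixel *and* per channel (the
  stronger reading of an ambiguous construction).
* Mask values stay floating point until application; quantization
  (round-half-up) happens once, when dots are subtracted from the patch.
* Dot-count rounding is half-up, making `sample_dot_count()` well defined
  at ties.
* Coordinates are 0-based (x = column, y = row); channel order is BGR
  end-to-end, converted explicitly at PNG boundaries.

Real slide backgrounds are not available to a self-contained package, so
`generate_background()` synthesizes a haematoxylin-*like* field: a pale
bluish base with smooth low-frequency variation, darker elliptical
nucleus-like regions (red attenuated more than blue, as haematoxylin
does), fine Gaussian pixel noise, and per-channel floors set just above
the darkest dot-centre colour so the painted dots remain the darkest
objects. This emulates the colour statistics and clutter of tissue, *not*
its texture realism: passing tests demonstrate that the pipeline's
mechanism works end to end on data whose ground truth is known exactly —
they do not measure performance on real stained tissue, where background
structures can mimic dots far more closely.

## Evaluation

Predictions and ground truth are matched one-to-one within an inclusive
Euclidean tolerance (default 5 px) by maximum-cardinality bipartite
matching, so the score is invariant to point order (a greedy mode exists
for sensitivity analysis; the suite shows it can be strictly worse).
Matched pairs are true positives; precision, recall and F1 follow, with
empty-versus-empty scored as perfect agreement on absence. Patch-level
reports are micro-aggregated (counts summed, ratios recomputed).

## Problem sizes in the test suite

The published configuration trains for 1664 epochs at 224x224 with a
"base" backbone — a multi-day GPU workload that no test reproduces. The
suite instead validates mechanisms at desk scale, chosen once: the
end-to-end recovery test generates 64 training and 16 held-out 128x128
patches, trains the `"tiny"` preset for ~30 epochs with Tversky
\(\alpha = 0.6\) under Adam (no augmentation: synthetic train and test
data already come from the same distribution), sweeps the threshold
surface for the best of the final two checkpoints, and requires F1 of at
least 0.60 — evidence that generator, network, training, calling and
scoring compose correctly, not a reproduction of the published score.
Short overlap-loss trajectories fluctuate epoch to epoch, which is why
two late checkpoints are scored rather than one. Oracle suites (matching,
flood fill, gradient checks) run on hundreds of small random instances
under fixed seeds.

## Known limitations

* The engine is CPU-bound, double-precision, single-threaded R/C++; it is
  meant for correctness and desk-scale experiments, not production
  training throughput.
* Backgrounds are statistical stand-ins; stain variation beyond the
  yellow-brown dot axis and slide-level artefacts are not modelled, and no
  stain normalization is provided (it tends to erase weak RNAscope
  signal).
* Sub-pixel localization and intensity-weighted centroids are out of
  scope; coordinates are integer pixels.
* The exact tile-overlap voting and patch-subdivision scheme of the
  original training setup is not public; random crops (train) and a
  stride-128 grid with max-stitching (eval) are this package's choices.
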