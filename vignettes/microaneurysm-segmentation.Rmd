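---
title: "Ensemble patch-based segmentation of retinal microaneurysms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble patch-based segmentation of retinal microaneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maseg)
```

## The problem

Microaneurysms (MAs) are tiny outpouchings of retinal capillaries and the
earliest visible lesion of diabetic retinopathy. In a color fundus
photograph they appear as small, round, dark-red blobs, typically no more
than about 50 px across at full device resolution (reference devices
produce images around 2124 x 2056 px), which makes an MA several thousand
times smaller than the image that contains it. Downscaling a whole fundus
image to a size a segmentation network can ingest destroys them; `maseg`
instead segments full-resolution *patches* and reassembles the whole-image
answer.

The pipeline has three stages:

1. **Tiling.** The image is broken into fixed-size square windows
   (default 576 px) laid out on an overlapping grid (default 30 %
   overlap). Per axis the window origins are `0, s, 2s, ...` with stride
   `s = floor(window * (1 - overlap))`; if the last regular origin leaves
   a gap at the border, one extra window is anchored flush with the edge.
   All-black windows (the corners outside the circular field of view) are
   discarded when building *training* sets, but never at inference, where
   full coverage is required for reconstruction.
2. **Patch segmentation.** Each window is segmented by three
   encoder-decoder networks -- U-Net, ResNet34-UNet and U-Net++ -- whose
   per-pixel foreground probabilities are averaged by the ensemble.
3. **Reconstruction.** Patch probability maps are accumulated on a
   whole-image canvas in the positions they were cropped from; each pixel
   is divided by the number of windows covering it; pixels whose averaged
   probability is *strictly greater* than 0.5 become MA (ties go to
   background).

Evaluation is purely pixelwise. With ground truth GT and segmentation S,
`TP = |GT AND S|`, `FP = |(GT OR S) - GT|`, `FN = |(GT OR S) - S|`, and

- IoU (Jaccard) `= TP / (TP + FP + FN)`,
- Dice (F1) `= 2 TP / (2 TP + FP + FN) = 2 IoU / (1 + IoU)`.

When both masks are empty all three counts are zero; `maseg` defines both
scores as 1 (perfect agreement on absence) and flags the case as
degenerate, since 0/0 is otherwise undefined.

## The three architectures

No deep-learning framework is involved: the package carries a compact
computational-graph engine (compiled convolution, transposed-convolution,
pooling, upsampling and batch-normalization kernels with hand-derived
reverse-mode gradients, verified against finite differences in the test
suite). All three builders share one contract: input `H x W x 3` in
[0, 1], output an `H x W` probability map, output size equal to input
size.

**U-Net** (reference: input 576, depth 5, widths 16/32/64/128/256,
bottleneck 512). Each encoder stage is two 3x3 convolutions with batch
norm and ReLU followed by 2x2 max pooling; after five stages a 576-px
input reaches an 18 x 18 x 512 bottleneck. The decoder mirrors the
encoder with 2x2 transposed convolutions and skip concatenations. The
head is a 1x1 convolution with a two-channel softmax; training minimizes
the two-class cross-entropy, which on a softmax pair is the same
criterion as binary cross entropy on the foreground probability. This
reference configuration has 7,781,634 trainable parameters. The published
description of this architecture family pins only the bottleneck shape
and an approximate 7.7 M count, which more than one width schedule can
satisfy; the 16-to-256 doubling schedule is this package's documented
choice, not a claim of bit-level fidelity.

**ResNet34-UNet** (reference: standard ResNet34 body, decoder widths
256/128/64/32/16). The encoder is the ResNet34 convolutional body: a 7x7
stride-2 stem, 3x3 stride-2 max pool, then residual stages of 3/4/6/3
blocks at widths 64/128/256/512. Each residual block is
conv-BN-ReLU-conv-BN with the input added back before the final ReLU (a
1x1 projection aligns shapes on stage transitions). The decoder has five
transposed-convolution blocks with skip concatenations from the residual
stages and the stem; the original input image is concatenated before the
final block so the head sees raw pixel values. An *additive attention
gate* re-weights each skip connection: the skip and the upsampled decoder
feature are projected to a common width, summed, passed through ReLU and
a 1x1 sigmoid head, and the resulting single-channel map multiplies the
skip. The gate follows the standard additive formulation and sits behind
a flag (`attention_gates`, on by default) because only its presence, not
its equations, is pinned by the architecture description we follow.
Reference count: 24,449,277 trainable parameters. No pretrained encoder
weights ship with the package; `pretrained_encoder = TRUE` raises an
error rather than silently downloading anything, and all reported counts
are weight-independent.

**U-Net++** (reference: depth 4, widths 32/64/128/256/512). Nested dense
skip connections: node `X(i, j)` receives the upsampled `X(i+1, j-1)`
concatenated with every earlier node `X(i, 0..j-1)` at its resolution.
With the nested nodes removed the connectivity reduces to a plain U-Net,
which the tests exercise. Deep supervision (1x1 heads on `X(0, 1..4)`
averaged at the output) is available behind `deep_supervision` but off by
default: the ensemble averages member probabilities anyway, and head
pruning is a head-selection question rather than weight surgery. The
reference build lands at 9,049,506 parameters; the corresponding
published model is reported at 9.1 M, but since its exact schedule is not
reconstructible from the text we do not treat that number as a target.

**Ensemble.** The combiner is the pixelwise arithmetic mean of the three
member probability maps, taken *before* thresholding -- consistent with
the reconstruction flow, which also averages probabilities before the
single final threshold. Majority voting is available (`combine = "vote"`)
for comparison. The mean can never leave the min-max envelope of the
members, so an ensemble cannot be worse than its worst member by more
than the members disagree among themselves.

## Training protocol

Patches are split by a seeded uniform shuffle into 70 % train / 10 %
validation / 20 % test (`floor` sizes, remainder to test: 1,000 patches
give exactly 700/100/200). Optimization is Adam (default learning rate
1e-3, batch size 8) on the two-class cross-entropy; weight initialization
is He-normal, seeded, and batch-norm layers keep running statistics for
inference. The weights returned are those of the epoch with the best
validation Dice, pooled over validation patches. Every stochastic step --
generation, splitting, initialization, shuffling -- flows from explicit
seeds, and a fixed seed reproduces bit-identical losses and masks on one
machine.

Hyperparameters beyond the optimizer family and loss are not pinned by
the method description this package follows; the defaults above are
documented package choices.

## The synthetic data generator

The clinical datasets such pipelines are trained on are not publicly
distributable, so `maseg` ships a seeded generator that emulates the
features of a fundus photograph that this pipeline actually interacts
with: a circular illuminated field of view on a black frame (the source
of all-black corner patches), a reddish textured background with a radial
illumination falloff, darker curvilinear vessel-like structures (smoothed
random walks) acting as confusers, and non-overlapping round dark-red
blobs with a sigmoidal soft edge whose exact pixel supports are written
to the ground-truth mask. Blob diameters are drawn uniformly from 5-50 px
by default, centers keep a margin of at least one diameter from the field
of view edge, and placement is rejection-sampled with bounded retries (an
error names the constraint when the requested blobs cannot fit). Masks
follow the annotation file convention: black = MA, white = background.

What the generator does **not** model: real lesion texture,
hemorrhages and exudates, optic disc and macula, camera noise structure,
inter-device color shifts, or annotator disagreement. Passing the
synthetic end-to-end benchmark therefore demonstrates that the mechanics
of the pipeline (tiling, training, ensembling, reconstruction, scoring)
work and that the networks can learn a nontrivial color-and-shape
discrimination; it says nothing about clinical performance, and the
package makes no claim to reproduce the headline clinical scores of the
method it implements, which required a proprietary dataset and days of
GPU training.

## Numerical choices and degenerate inputs

- **Initialization.** Convolution weights are He-normal and seeded.
  Two standard stabilizers keep the deep residual encoder trainable from
  any seed: the second batch-norm gamma of every residual block starts at
  zero (each block begins as the identity, so the 16-block encoder
  behaves like a shallow network early in training), and each attention
  gate's sigmoid head starts open (bias +3, near-zero weights) because a
  randomly saturated gate blocks both the skip signal and its gradient.
  Scaled-down ResNet34-UNet decoders floor their stage widths at 8
  channels -- narrower tails develop seed-dependent dead units that can
  stall learning entirely; the reference widths (256/128/64/32/16) are
  unaffected.
- **Stride rounding.** `floor(window * (1 - overlap))` guarantees an
  integral stride and at least the requested overlap.
- **Edge windows.** Anchoring the last window flush to the border adds
  extra overlap there instead of padding, so lesion pixels near the edge
  are seen at their original scale.
- **Reconstruction exactness.** Accumulation is order-invariant;
  averaging k identical contributions reproduces the original value up to
  one unit in the last place (exactly, when k is a power of two), which
  is why round-trip tests assert equality at 1e-12 rather than bitwise.
- **Threshold ties.** Strictly-greater-than comparison: probability
  exactly 0.5 is background.
- **Black-patch rule.** A patch is discarded only if *every* channel of
  *every* pixel is at or below `black_tol` (default 0): one intensity
  step above pure black already keeps a patch.
- **Both-empty metrics.** IoU = Dice = 1 with a degenerate flag, see
  above.
- **Uncovered canvas pixels.** `finalize_map()` refuses to divide where
  the overlap count is zero and reports an offending pixel, which guards
  against accidentally discarding windows at inference.

## Desk-scale benchmark sizes

The end-to-end check trains scaled-down versions of all three
architectures -- window 64, base width 8, depth 3 for U-Net and U-Net++,
the full 16-block residual layout at one-eighth width for ResNet34-UNet
-- on 30 synthetic 320 x 320 images (about 1,470 patches, split
70/10/20) for 3 epochs each, then scores pooled Dice on the held-out
patches. These sizes are the package's choice of a benchmark that a
single CPU completes in minutes while still exercising every stage at
realistic overlap counts; the self-imposed bar is Dice at least 0.5 per
member with the ensemble at least matching its weakest member, which a
correct implementation clears with a wide margin (the seeded benchmark
run reported in the README reaches pooled Dice 0.94-0.96 for the members
and 0.955 for the ensemble).

## Known limitations

- The engine is CPU-only and double-precision; it is built for
  correctness and desk-scale experiments, not for training
  full-resolution clinical models.
- Only the mean and majority-vote combiners are implemented; learned
  fusion is out of scope.
- Per-lesion (object-level) detection metrics are deliberately absent:
  scoring is pixelwise, matching the evaluation protocol the package
  implements.
- The U-Net++ deep-supervision heads average logits; per-head loss
  weighting during training is not implemented.
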