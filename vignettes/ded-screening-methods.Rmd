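---
title: "Methods: classical preprocessing and a compact CNN for diabetic eye disease screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classical preprocessing and a compact CNN for diabetic eye disease screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Early diabetic eye disease (DED) — mild diabetic retinopathy (DR), mild
diabetic macular edema (DME) and early glaucoma — leaves only faint traces in
a color fundus photograph: microaneurysms a few pixels wide, low-contrast
exudate deposits, subtle optic-disc changes. Deep classifiers trained on raw
photographs routinely miss these mild cases. `dedscreen` implements a
screening pipeline built on the opposite premise: classical image processing
first makes the lesions explicit (contrast enhancement, vessel and optic-disc
segmentation, exudate localization), and only then does a compact CNN
classify the normal-versus-mild problem. The package also ships a synthetic
fundus generator with pixel-level ground truth, so every stage is
quantitatively testable without access to clinical datasets.

## Enhancement operators

All operators act on the **green channel**, where the vessel/background
contrast of a fundus photograph is highest, quantize with round-half-up, and
replicate edges at borders so output dimensions always equal input
dimensions.

**CLAHE.** Contrast-limited adaptive histogram equalization splits the image
into tiles (default 32 x 32 px), equalizes each tile's histogram after
clipping it at `n_cl = clip_factor * n_avg`, with `n_avg = tile_rows *
tile_cols / gray_levels` the average bin count, and blends the four
surrounding tile mappings bilinearly at every pixel. Clipped mass is
redistributed uniformly over all bins in a single pass. The clip factor
(default 2) bounds noise amplification in flat regions: an unclipped
equalization would stretch pure sensor noise across the full dynamic range.

**Illumination correction.** Fundus photographs are unevenly lit; each pixel
becomes `p' = p + desired_mean - local_mean` with the local mean taken over
an odd sliding window (default 31 px). For a linear illumination ramp the
local mean reproduces the ramp exactly away from borders, so the correction
flattens it to the target mean within quantization error — a property the
test suite checks directly.

**Contrast stretching.** The min-max stretch maps the observed range
affinely onto `[0, gray_levels - 1]` as
`(mu - min) / (max - min) * (Gamma - 1)`. A sign-flipped variant of this
quotient, `(mu - max) / (min - max)`, circulates in the literature and
*inverts* contrast; since the operator's purpose in this pipeline is
enhancement, the standard orientation is used. A constant image raises a
degenerate-input error rather than dividing by zero; callers may skip the
stage.

**Median filter.** Odd-window sliding median with edge replication, checked
pixel-for-pixel against a brute-force window-sort oracle.

## Morphology

Erosion, dilation, opening and closing follow the set definitions with
out-of-image pixels treated as background in both directions: the structuring
element must fit inside the foreground for erosion and out-of-bounds
positions contribute nothing to dilation. This convention makes the
erosion-dilation duality exact on interior pixels (the complement flips the
implicit padding on the frame, so the tests compare away from it) and means
closing is extensive only for masks embedded off the frame — the practical
case for vessel masks. The default structuring element is the 3 x 3 full
square with centered origin; no stage of the pipeline requires a larger one
except the optic-disc refinement (5 x 5 closing to bridge vessels crossing
the disc rim).

## Segmentation

**Vessels.** Green channel, CLAHE, illumination correction, then the ISODATA
(intermeans) threshold: the fixed point of `t <- (mean below t + mean above
t) / 2`, iterated from the global mean to a 0.5-intensity tolerance. The
darker class is the vessel candidate; closing bridges small gaps and
components under 20 px are dropped. Because thresholding always produces a
dark class, a plausibility guard returns an empty mask when that class spans
more than 35% of the field — the vasculature occupies roughly a tenth of a
fundus image, while the symmetric split of a vessel-free noise field puts
half the pixels below threshold.

**Optic disc.** The brightest circular structure. After CLAHE (plus a
min-max stretch when the dynamic range is under three quarters of full
scale) and a 3 x 3 median filter, a gradient-magnitude edge map (threshold at
the 90th percentile of positive magnitudes) feeds a circular Hough transform
at 1 px resolution in center and radius, with the default search radius
between 1/20 and 1/6 of the image side — plausible disc proportions.
Candidates are ranked by raw votes; ties break toward the smaller radius and
then row-major center order, so detection is fully deterministic. Two gates
reject spurious maxima: the best circle must collect at least 35% of its
circumference in votes *and* at least 2.8 times the coincidental-vote
expectation (edge density times the circle's rasterized perimeter, about
`1.42 * 2 * pi * r` cells). On synthetic fields these gates separate cleanly:
noise-only images reach vote fractions of ~0.29 and SNR ~2.7, genuine discs
sit at 0.42-1.1 and 3.1-7. The disc mask is the filled detected circle
extended by bright pixels (Otsu threshold inside a bounding box of 1.5 times
the detected radius, restricted to 1.3 radii) and closed with a 5 x 5
element, which restores the rim pixels occluded by vessels.

**Exudates.** The disc mimics exudate brightness, so it is removed first
(background-mean fill), then vessels (neighborhood-mean fill over a 7 x 7
window, preventing dark residue from forming a spurious histogram class).
Otsu's threshold — selected by exhaustive maximization of the between-class
variance, with the full weight/mean/variance bookkeeping exposed — marks the
bright class as candidates, refined by a 3 x 3 opening and the exclusion of
any remaining disc pixels. Two guards reject lesion-free images, whose
near-unimodal histograms Otsu would still split: candidates are discarded
wholesale when the bright class covers more than 5% of the image (exudates
are small) or when the class means are separated by fewer than 25 intensity
units (exudates are high-contrast). The Otsu statistics satisfy
`within + between = total variance` to 1e-9 at every candidate threshold;
the implementation uses the standard `(i - m_k)^2` class variances — the
only form under which that decomposition (asserted by the method itself)
holds — and sums the global mean over gray levels.

## Synthetic fundus generator

The generator emulates what the segmentation stages need to be tested
against, at toy scale: an orange-red background, a linear illumination ramp
(peak-to-peak 20 intensity units) that exercises the correction step, a
bright optic disc of 9-12% of the image side with a ~2 px soft rim, a
recursively branching vessel tree (6 primary branches, 2-4 px wide, tapering
by 25% per generation over three generations) drawn over the disc as in a
real photograph, and Gaussian sensor noise (sd 3). Class labels control the
lesions: `mild_dme` adds 2-4 bright Gaussian blobs (sigma 2.2-3.2 px, mask
at half maximum) on the macular side, off the disc and the vessel tree;
`mild_dr` adds 1-2 px dark dots near vessel midpoints; `mild_gl` enlarges
the disc by 30%. Everything is deterministic in `(config, label)`: per-image
RNG streams are derived from the seed, so datasets are reproducible
byte-for-byte.

Defaults are free choices: the screening protocol fixes 100 images per
class and binary normal-versus-mild contrasts, but lesion size and contrast
distributions for "mild" disease are not prescribed anywhere, so they were
chosen once at plausible toy-scale values. What passing tests
show is therefore that each operator implements its definition and that the
pipeline recovers planted structure (vessel Dice >= 0.6, disc center within
5 px, exact exudate counts); they do not show clinical performance. Real
fundus photographs add camera vignetting, 45-degree field-of-view geometry,
pigmentation variation and focus blur that the generator deliberately omits.

## Model builders and the training engine

The proposed classifier is five blocks of same-padded 5 x 5 convolution
(stride 1; 64, 128, 256, 512, 512 filters) each followed by 2 x 2/stride-2
max pooling and ReLU, then flatten, dropout 0.5, a 64-unit dense layer and a
classification head. At the 224 px input the spatial chain is 224 -> 112 ->
56 -> 28 -> 14 -> 7 and the flattened width is 25,088; the input side,
same-padding and the 5 x 5 fifth-layer kernel are the only choices under
which that chain, the 7 x 7 x 512 final tensor and the 25,088 flatten are
simultaneously consistent (valid padding already breaks the 112 after the
first pool). The block order is conv -> pool -> ReLU; max-pool and ReLU
commute, so the placement is numerically neutral. Binary problems get a single
sigmoid unit with binary cross-entropy; multi-class heads use softmax.

Transfer bases (VGG16, Xception, DenseNet-121) are
declarative: the builders reproduce the published topologies exactly, as
verified by their 1000-class ImageNet parameter totals (138,357,544;
22,910,480; 8,062,504), and carry trainable flags for feature extraction
(base frozen) versus fine-tuning (last *n* parameterized layers unfrozen).
Weights are randomly initialized; loading published weight files would
require network access and is out of scope. The bundled training engine
supports the proposed CNN's layer kinds (im2col convolutions over BLAS,
pooling with first-maximum gradient routing, inverted dropout, RMSprop and
Adam); batch-norm/separable-convolution topologies are specification objects
only.

Hyper-parameters follow the study protocol: RMSprop for the proposed CNN
and Adam for transfer models, mini-batch 32, initial learning rate 3e-4,
binary cross-entropy, stratified 80/20 splits and stratified 10-fold
cross-validation. Augmentation (flips, rotation, cropping; "mirror" treated
as a synonym of horizontal flip) is a seeded per-epoch stream that yields
exactly one variant per image per epoch and never enlarges the stored
dataset. Non-right-angle rotations use bilinear resampling with edge
replication; no interpolation scheme is prescribed by the protocol, and
bilinear matches the CLAHE stitching choice.

## Desk-scale experiment

`screening_experiment()` runs the whole pipeline end to end at a size chosen
for a single CPU: 100 synthetic images per class (normal vs mild DME) at
128 px, a reduced proposed-CNN variant (64 px input, filter banks scaled by
1/16 to 4-8-16-32-32), 10 epochs, stratified 80/20 split. Two arms share
seeds and budgets: raw RGB inputs versus the lesion-emphasizing
representation from `preprocess_for_training()` (enhanced green channel;
green channel with disc and vessels removed; exudate-candidate mask). On
synthetic data the preprocessed arm reaches test accuracy at or near 100%
while the raw arm, given the same 10 epochs, stays far lower — the
improvement direction the classical-first premise predicts when moving from
raw to preprocessed inputs. The reduced filter banks and epoch budget are
the deliberate scale
of this experiment, not tuned quantities; the accuracy figures are computed
fresh on every run (see `scripts/acceptance.R`).

## Numerical choices and degenerate inputs

* Round-half-up after every enhancement stage; values clamped to
  `[0, gray_levels - 1]`.
* Constant images: contrast stretch and ISODATA raise degenerate-input
  errors; single-bin histograms are rejected by the Otsu routine.
* Otsu ties break toward the smallest threshold; CHT ties toward the
  smallest radius, then row-major center order.
* Coordinates are 1-based `(row, col)` from the top-left corner, R's native
  matrix convention.
* `remove_region` pixels with no unmasked neighbor in the window fall back
  to the background mean.
* Optic-disc detection failure is an error by contract; the dataset-level
  wrapper `preprocess_for_training()` degrades to an empty disc mask
  instead, because one undetectable disc should not abort a training run.

## Known limitations

The generator's simplicity means segmentation scores here are upper bounds,
not estimates, of real-data performance. The CNN engine is single-threaded
R; it is sized for the desk-scale experiment, not for 224 px training runs.
Transfer models are architecture specifications with exact parameter
accounting, not trainable networks, in this package. ROC utilities sweep
thresholds over predicted scores but no claims are made about real-data
operating points.
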