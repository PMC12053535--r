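---
title: "GTVseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GTVseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

GTVseg is a desk-scale toolkit for patch-based 3D semantic segmentation of
head-and-neck gross tumor volumes (the primary tumor, GTVp, and metastatic
lymph nodes, GTVn) on T2-weighted MRI. It packages a particular U-Net
*configuration* — patch-wise intensity normalization, a scheduled
augmentation policy, Gaussian-weighted sliding-window inference, and a
present-class batch Dice loss — together with the NIfTI plumbing, a
synthetic phantom generator, and a small training workbench, so that every
piece of the configuration can be exercised and tested end to end on a
single CPU. This vignette records the model, the tunable parameters, and
the design decisions that were genuinely open.

## The segmentation problem and the data model

Inputs are 3D scalar volumes with voxel spacing in mm (class `Volume`) and
integer masks over {0 = background, 1 = GTVp, 2 = GTVn} (`LabelMask`).
Throughout the package, voxel indices are 0-based and the axis order is
(x, y, z), matching the order of the spacing vector. Images are reoriented
to the RAS canonical orientation on read; `originMeta` records the source
grid (shape, spacing, orientation, header) so that predictions can be
restored exactly to the grid of the input file with `restoreToOrigin()`.
Volumes are resampled with trilinear interpolation and masks with
nearest-neighbor only, so no fractional label can ever appear; the output
shape per axis is `round(shape * spacing / target)` with ties away from
zero (the rounding rule is a package decision — any fixed rule works, but
it must be fixed). The working resolution used for full-scale head-and-neck
scans is 0.5 x 0.5 x 2 mm; phantoms are generated at 1 x 1 x 2 mm.

## The network

The architecture is a plain six-stage 3D U-Net built from convolutional
blocks (3D convolution, instance normalization with learnable affine,
ReLU), with 2x2x2 max pooling between encoder stages and channel doubling
after each pooling; the decoder enters each stage through a 1x1x1
convolutional block that halves the channel count, doubles the resolution
by nearest-neighbor interpolation, concatenates the encoder skip from the
same stage, and applies two more blocks. A 1x1x1 convolution plus softmax
produces three class probabilities per voxel.

The configuration knob that matters is `kernelByStage`: with base width 32
and two blocks per stage, 3x3x3 kernels everywhere give roughly 86 million
trainable parameters, while switching stages 5-6 (and decoder stage 5) to
1x1x1 kernels cuts this to roughly 14 million without touching the
receptive field of the high-resolution stages. `countParameters()`
enumerates exactly the arrays `buildUNet()` allocates, so the two can never
disagree.

The network is implemented natively in R with a hand-written
forward/backward pass. Convolutions are evaluated by physically
zero-padding the feature grid and issuing one BLAS `dgemm` per kernel
offset with shifted row pointers (`src/conv3d.cpp`); the input gradient is
the convolution of the output gradient with the offset-reversed,
channel-transposed kernel, which avoids any scatter-add. A
finite-difference gradient check over every layer type is part of the test
suite. Instance normalization uses the population variance with epsilon
1e-5. He initialization is used for convolution weights; biases start at
zero and instance-norm affines at identity.

### Frozen normalization statistics

Instance normalization recomputes its statistics from whatever input it is
given, so a network evaluated on a patch is not the same function as the
network evaluated on the whole volume — even when every kernel is 1x1x1.
`freezeNormStats()` captures the per-block statistics on a reference input
and reuses them at inference (ordinary eval-mode semantics). An
all-1x1x1-kernel network with frozen statistics is strictly voxelwise,
which is what makes the exact sliding-window/whole-volume equivalence test
possible; at pooling-aligned strides the max-pool blocks also partition
identically, and the equivalence holds to floating-point precision. This
is a testing device, not part of the training recipe.

## Patch sampling and normalization

Training patches (default 320 x 320 x 64 at full scale; 32 x 32 x 16 for
the desk-scale phantom recipe) are sampled so that 90% contain at least one
target-class voxel: a target voxel is drawn uniformly, then the patch start
is drawn uniformly among starts covering it. The remaining 10% (and all
draws on tumor-free images) are uniform over valid positions. The
mechanism is the simplest one satisfying the stated contract; volumes
smaller than the patch are zero-padded symmetrically (the padding value is
applied before normalization, and a constant padded patch normalizes to
zeros by the zero-variance guard).

MRI intensity scales are arbitrary: different scanners, coils and export
pipelines produce different global scales, offsets and smooth bias fields.
`normalizePatch()` z-scores each patch *after* extraction (population sd,
tolerance 1e-5), which makes the model input exactly invariant to
per-image affine intensity maps — `normalize(a*x + b) == normalize(x)` for
any a > 0 — and pins the first two moments of every input regardless of
patch location. The conventional baseline, image-wise normalization
(`normalizeVolume()`), is also provided: there the patch statistics depend
on where the patch was cut, a location-dependent covariate shift that the
patch-wise mode eliminates. At inference the same per-patch normalization
runs inside the sliding-window loop, so training and inference inputs
follow the same distribution. In the prior-guided 4-channel mode the two
binary prior-mask channels bypass normalization.

## Augmentation and its schedule

Six transforms fire independently per patch with a shared probability:
mirroring (one axis, chosen uniformly), in-plane rotation (bilinear for the
image, nearest-neighbor for the mask), gamma contrast, a smooth
multiplicative bias field, ghosting-style motion imitation, and additive
Gaussian noise. Spatial transforms move image and mask identically; the
mask label set can never grow. The probability follows
`pStart + (pEnd - pStart) * k/(K-1)` over 1000-batch blocks, from 0.05 in
the first block to exactly 0.25 in the last — the endpoint convention
`k/(K-1)` is forced by requiring both endpoints to be attained.

Parameter ranges are package choices, each one config key: rotations
uniform within ±15° (in-plane only by default, respecting the strongly
anisotropic voxels), gamma in [0.8, 1.25], bias-field amplitude up to 0.3,
ghosting shift up to 4 voxels at blend weight up to 0.2, noise sd up to
0.1 of the patch sd. Augmentation runs *before* normalization so the
perturbed statistics are re-standardized; the ordering is a package
decision. In the 4-channel prior-guided mode the training loop skips
augmentation rather than inventing a multi-channel-consistent variant.

## Loss and metrics

The per-pair Dice similarity coefficient is
`DSC = 2|y ∩ ŷ| / (|y| + |ŷ|)`. For cohort evaluation the aggregated form
pools intersections and sizes over all pairs before dividing:

    DSCagg = 2 Σₙ |yₙ ∩ ŷₙ| / Σₙ (|yₙ| + |ŷₙ|)

which keeps tumor-free patients informative — their false positives
enlarge the pooled denominator instead of yielding an uninformative
per-patient 0. The training loss is the smooth batch analogue: per class,
`1 − 2 Σ y·p̂ / (Σ y + Σ p̂)` with sums over the entire batch, averaged
over the classes *present* in the batch ground truth (background
included); absent classes contribute nothing. Presence is decided from the
ground truth alone. A tiny epsilon (1e-7) guards the all-zero-prediction
denominator; no other smoothing is used because presence-masking already
prevents 0/0. Empty-empty pairs score 1 ("vacuously perfect"), a
convention exposed as an argument; the all-empty DSCagg denominator
follows the same convention.

## Sliding-window inference

Whole volumes are predicted over a window grid that starts at 0, steps by
the stride, and clamps the final start to `volume − patch` so the last
window ends flush with the edge — full coverage with no padding for
volumes at least as large as the patch (smaller volumes are padded and
cropped back). Per-patch probabilities are blended as
`Σ wᵢ p̂ᵢ / Σ wᵢ`; since the weights cancel on voxels covered once, the
weight map only shapes overlap regions, and the blended output remains a
probability simplex everywhere. The default Gaussian map is the separable
product of per-axis profiles `exp(−d²/2σₐ²)` with σₐ chosen in closed form
so the profile equals the edge value (default 0.1) at the boundary voxel
of each axis: faces get 0.1 and corners 0.001. "Edges" is read per-axis —
the corner value is the product of three axis profiles; a radial
construction would be the other defensible reading. For even axis lengths
no voxel sits at the continuous center, so each profile is renormalized by
its maximal voxel value to keep the map's maximum exactly 1. Labels are
the voxelwise argmax with ties broken toward background, predictions of an
ensemble average the softmax outputs before the argmax, and the final mask
is restored to the input's original grid by nearest-neighbor resampling.
No post-processing (e.g. connected-component filtering) is applied.

## Training workbench

`trainUNet()` wires the pieces together: per iteration it samples a batch
(default size 2) with the 90/10 rule, augments at the scheduled
probability, normalizes, runs the forward pass, computes the present-class
Dice loss, and takes an Adam step (betas 0.9/0.999, eps 1e-8 — left at
conventional values) at a cosine-decayed learning rate,
`lrEnd + (lrStart − lrEnd)(1 + cos(π t/T))/2`, from 1e-3 down to 1e-5.
Every `evalEvery` iterations the validation patients are segmented by
sliding-window inference and per-class DSCagg is logged; the checkpoint
with the best validation mean over (GTVp, GTVn) is retained — never the
training loss. Cross-validation folds are patient-wise: all images of a
patient share one fold. Everything is reproducible from (config, seed).
Training runs in full precision throughout.

## The phantom generator

Phantoms emulate the specific properties the configuration targets, not
anatomy: a band-limited random background (trilinearly upsampled coarse
Gaussian grid, mean ~100), disjoint ellipsoidal lesions with GTVp at +30%
and GTVn at +50% of the background mean, a smooth multiplicative quadratic
bias field (amplitude 0.2 by default), a per-image global intensity scale
and shift (log-uniform scale in [0.5, 5], shift in [0, 50] across a
cohort — the non-standardized MRI scale), and additive Gaussian noise (sd
0.05 of the background mean). The paired generator reuses the same anatomy
and grid and shrinks every lesion about its center (treatment response);
shrink 0 produces the tumor-free case that exercises the empty-truth
DSCagg path. Lesion contrast, bias amplitude and noise level are fixed
documented choices. What passing tests on phantoms demonstrate is that the
*mechanisms* work — affine-intensity invariance, fold hygiene, loss/metric
identities, convergence of the optimization; they say nothing about
segmentation accuracy on real anatomy, soft-tissue boundaries, or
inter-observer ambiguity, none of which the generator attempts to model.

## Desk-scale problem sizes

The test-suite training recipe uses 96 x 96 x 48 phantoms at 1 x 1 x 2 mm,
patches of 32 x 32 x 16, a three-stage U-Net of base width 6, batch size
2, and 2000 iterations with validation every 500 — sizes chosen so a full
end-to-end run with cross-validation bookkeeping completes in minutes on
one CPU while still exercising every code path (multi-stage pooling, skip
concatenation, scheduled augmentation, sliding-window validation,
checkpoint selection). The base width of 6 is the smallest that reliably
separates the two lesion classes at this scale: narrower nets collapse
GTVp and GTVn into one class within the 2000-iteration budget. The
full-scale recipe (320 x 320 x 64 patches, base width 32, 100K
iterations) is expressible in the same configuration objects but is far
outside desk scale.

## Known limitations

* The native-R training loop is single-threaded and desk-scale by design;
  it is a correctness-first reference, not a GPU replacement.
* Rotations are in-plane only by default; 3D rotations of anisotropic
  voxels would require resampling decisions the package does not take.
* The motion transform imitates ghosting by shifted-copy blending; it is
  not a k-space simulation.
* Multi-channel (prior-guided) training currently runs unaugmented.
* Orientation handling restores the source orientation on write but does
  not preserve oblique affines beyond the header copy; DICOM ingestion,
  bias-field correction and registration are out of scope.
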