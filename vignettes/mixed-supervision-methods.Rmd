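---
title: "Mixed-supervision detection and segmentation of acute infarct on DWI/ADC MRI"
author: "infarctSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-supervision detection and segmentation of acute infarct on DWI/ADC MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute ischemic infarct shows *restricted diffusion* on MRI: the lesion is
hyperintense on the diffusion-weighted series (DWI, B-1000) and hypointense
on the apparent diffusion coefficient map (ADC). Both series are needed:
T2 shine-through produces DWI hyperintensity *without* ADC darkening and is
a classic false-positive source. Clinically useful automation must answer
two questions at once — *is there an infarct?* (triage) and *where and how
large is it?* (lesion volume is a thrombectomy selection criterion).

infarctSeg implements a single network that answers both. It produces a
voxel-level probability map; the study-level probability is simply the
maximum voxel probability (a global max-pooling head — if any voxel is
positive, the study is positive); the lesion volume is the aggregation of
supra-threshold voxels times the voxel dimensions.

## Model

The segmentation backbone is an encoder–decoder ("U-Net") over the paired
DWI/ADC channels with one deliberate asymmetry: **pooling acts only within
the axial plane**. Downsampling max-pools by 2 in x and y and never in z,
and upsampling mirrors that, so the full z resolution is preserved and the
network runs on any number of axial slices without z-resampling (which
tends to wash out small infarcts). Convolutions are 3×3×3 with batch
normalization and a leaky ReLU (negative slope 0.3); the output layer is a
1×1×1 convolution with a sigmoid. Channel widths start at `baseChannels`
(default 16) and double at each of `depth` (default 3) pooling levels, with
two convolution blocks per level and concatenating skip connections;
upsampling is nearest-neighbour ×2 followed by convolution. The input x/y
dimensions must be divisible by 2^depth.

### Mixed supervision

Studies come in three supervision classes: *segmented positives* (label +
voxel mask), *classification-only positives* (label only), and *negatives*
(whose masks are known to be empty). The loss has two equally weighted
terms:

* binary cross-entropy between the max-pooled study probability and the
  study label, over **all** studies in the batch;
* a soft Dice loss, `1 − (2·Σpt + ε)/(Σp + Σt + ε)` with `ε = 1`, over
  the **Dice-eligible** subset only: segmented positives and negatives
  (with empty target masks). Classification-only positives contribute no
  Dice term; their entire voxel map receives gradient only through the
  argmax voxel of the classification head.

With `ε = 1` the empty-vs-empty case is exactly lossless, which is what
makes the Dice term applicable to negatives. Every batch holds 8 studies
with fixed composition 2 segmented positive / 2 classification-only
positive / 4 negative, sampled with replacement within class, so scarce
segmented studies are oversampled rather than exhausted.

### 2D pretraining and weight inflation

Instead of training the 3D network from random initialization, a 2D
variant (identical architecture with 3×3 kernels) is trained first on
axial slices of the segmented positives plus an equal number of negatives
redrawn each epoch; classification-only positives are excluded because no
slice-level label exists for them. A slice's label is whether its mask
contains any positive pixel, and the same two-term loss applies at slice
level (every slice of these studies has a known mask, so all slices are
Dice-eligible). After pretraining, each 2D kernel initializes the central
axial plane of the corresponding 3×3×3 kernel, the other planes are zero,
and biases and batch-norm parameters are copied. Because pooling never
touches z, the inflated network is *exactly* slice-separable in inference
mode — its output equals the 2D network applied slice by slice — which the
test suite asserts to 1e-5 and which makes inflation a pure
initialization, not an approximation.

### Intensity normalization

Per series and per study, the 3rd and 97th intensity percentiles I3 and
I97 are computed over all voxels (linear-interpolation percentile
definition; no brain masking — the stated distribution is the whole
series). Then

    I_min = I3,   I_max = I97 + α (I97 − I3)

with α = 0 for ADC and α = 1 for DWI, so that strongly hyperintense
restricted-diffusion voxels on DWI are not saturated. Intensities are
clamped to [I_min, I_max] and scaled linearly to [0, 1]. Written
literally, the mapping returns raw-scale values at the clamps and a [0,1]
ratio elsewhere; the only self-consistent reading maps the clamped voxels
to 0 and 1, which is what `normalizeIntensities()` does. A constant volume
maps to all-zero.

### Augmentation

One geometric draw per study — rotation up to ±10° in plane, x/y
translation up to 10% of the image dimensions, a shared x/y scale factor in
[0.9, 1.1] — applied identically to DWI, ADC (bilinear) and mask (nearest
neighbour, re-binarized). Independently per series, a random offset of up
to 0.2·(I97 − I3) in either direction perturbs the I_min and I_max used to
scale the intensities; on the already-normalized volume this is a shift by
−δ/(I_max − I_min) followed by re-clamping to [0, 1], which is how it is
implemented. Out-of-frame voxels are filled with 0, the background value
after normalization.

### Optimization

Adam (β₁ = 0.9, β₂ = 0.999), initial learning rate 1e-4 for the 3D phase
and 1e-3 for 2D pretraining, with the rate divided by 10 after half of the
scheduled epochs and by 10 again after a further quarter (for the
reference 200-epoch schedule: epochs 100 and 150). The faithful schedule
is 200 3D epochs; one 3D epoch is defined as ⌈n_segmented / 2⌉ balanced
batches so each segmented positive is expected about once per epoch.
Training aborts with diagnostics on a non-finite loss; when a validation
set is supplied the checkpoint with the best validation AUROC is retained.

### Inference

`predictStudy()` normalizes, resizes in plane to the network grid, runs
the forward pass in inference mode (batch-norm running statistics), and
resamples the probability map back to the study's native grid with
bilinear interpolation. The study probability is the maximum of the
*native*-grid map and the call is made with an **inclusive** threshold
(probability ≥ operating point, default 0.5), so the binary call and the
predicted volume — supra-threshold native voxel count × dx·dy·dz / 1000 —
are exactly consistent: the volume is positive iff the call is positive.
Volumes are measured on the native grid because resizing distorts voxel
dimensions. Single-series ablation models (`dwi_only`, `adc_only`) are
separate 1-channel networks, not zeroed channels.

## Evaluation statistics

* **AUROC** is computed as the Mann–Whitney statistic (ties half-weighted)
  and is tested against an exhaustive O(n²) pair-counting oracle.
* **Confidence intervals** use study-level bootstrap resampling with
  10,000 iterations and the percentile method; single-class resamples are
  redrawn, and the metric is declared un-bootstrappable if more than half
  of the draws fail. Fixed seeds make the intervals bit-reproducible.
* **Dice** is evaluated on true positives only (positive by both ground
  truth and model), on the native grid.
* **Volume agreement**: Pearson correlation plus Bland–Altman mean
  difference and 95% limits of agreement (mean ± 1.96 sd of differences),
  overall and restricted to ground-truth volumes < 70 mL — the
  thrombectomy-relevant stratum. The quoted "95% CI" of the agreement
  analysis is interpreted and labelled as limits of agreement; the
  intervals are far too wide to be standard errors of the mean.
* **Spearman** rank correlation (midrank ties, two-sided p) relates the
  classification probability to covariates such as true lesion volume
  over ground-truth-positive studies.

## The phantom generator

Clinical MRI cohorts cannot be redistributed, so the package ships a
stroke-phantom simulator that makes every pipeline stage testable:

* an ellipsoidal "brain" of constant base intensity per series against a
  dark background;
* infarct lesions as unions of 1–3 overlapping spheres (radii 5–12 mm,
  jittered centres — deliberately not perfect spheres so that Dice < 1 is
  informative), with DWI intensity ×1.8 and ADC ×0.45 relative to brain;
* T2 shine-through confounders with probability 0.3 per study: a blob
  bright on *both* series (DWI ×1.6, ADC ×1.5), never part of the
  ground-truth mask — this is what defeats single-channel thresholding and
  motivates the paired-series input;
* additive Gaussian noise (sd 40 on a DWI brain of 400; sd 80 on an ADC
  brain of 800, ~10%), and an optional smooth multiplicative bias field
  behind a flag.

The default grid is 64×64×16 at (3.4, 3.4, 5.0) mm — slice thickness at
the 5 mm cohort-admission bound — small enough for CPU training. All
randomness derives from one master seed through a counter-based per-study
derivation, so a cohort is reproducible file-for-file, and the true
volume bookkeeping (mask voxels × voxel volume) is exact by construction.

What the phantom does **not** emulate: MR physics (no k-space, no
diffusion tensor), anatomy, partial-volume boundaries, scanner and
protocol variation, or the hemorrhage/tumor mimics seen clinically. A
model that passes the synthetic experiments has demonstrated that the
*mechanisms* work — normalization, mixed loss masking, inflation,
balanced sampling, thresholded volumetry — not that clinical-grade
accuracy is achieved on real data.

Because the phantom's lesions are homogeneous in contrast, a handful of
segmented examples can already determine the decision rule; the benefit of
adding classification-only studies is therefore muted relative to
clinical data, where mixed supervision measurably improved both
classification and segmentation. The ablation experiments in the test
suite accordingly check a weak ordering (mixed supervision not worse),
not the full clinical effect size.

## Problem sizes and numerical choices

Desk-scale experiments use a 200-study cohort at 64×64×16 (140 train /
60 held out, half of the training positives segmented) and a depth-3 /
base-16 network — the reference configuration of `runPhantomExperiment()`
and `scripts/acceptance.R`. The scaled-down schedule is 12 pretraining
epochs with single-study slice batches followed by one balanced 3D epoch;
the ablation comparisons run a smaller 32×32×8 / depth-2 / base-8
configuration. These sizes are the package's choice of a configuration
that a single CPU trains in minutes while still exercising every
mechanism; the faithful clinical-scale schedule (256×256 in-plane, 200
epochs, 16-study slice batches) is available through the same
configuration objects.

Other numerical decisions, made once where the method description is
silent:

* percentile definition: linear interpolation between order statistics
  (R's default `type = 7`);
* Dice smoothing ε = 1 in the loss; binary cross-entropy probabilities
  clamped at 1e-7;
* batch-norm statistics during training are those of the sample being
  processed (studies are processed one at a time; running averages with
  momentum 0.1 serve inference) — the slice-batch and volume-batch
  statistics regimes differ in any case, and the inflation equivalence is
  asserted in inference mode;
* bilinear interpolation for images and nearest-neighbour for masks, both
  for resizing and augmentation transport; out-of-bounds fill is 0;
* convolution weights initialize from a fan-in-scaled normal (He) with a
  seeded RNG;
* threshold comparisons are inclusive (≥), so the classification head and
  the 0.5-shaded probability maps agree at the boundary;
* the single-precision engine computes convolutions as im2col + GEMM; all
  statistics are accumulated in a fixed order, so results are
  reproducible for a fixed seed on a given BLAS.

## Known limitations

* The exact layer widths of the clinical model were not published; the
  canonical two-convolutions-per-level U-Net layout with configurable
  depth and base width stands in for it.
* DWI and ADC must share one voxel grid; no cross-series registration is
  attempted, and DICOM ingestion is out of scope (NIfTI-1 only).
* The classification-only gradient path flows through a single argmax
  voxel per study; with very short schedules this term is noisy, which is
  visible in the scaled ablation experiments.
* Inference wall-clock depends on hardware and is not a tested property.
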