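---
title: "Auto-segmentation of the tubarial glands from CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-segmentation of the tubarial glands from CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The tubarial glands are bilateral salivary-gland-like tissue in the
posterior nasopharynx, visible on PSMA PET through radiotracer uptake
but essentially invisible on CT. Because radiotherapy planning is
CT-based and PSMA PET is not part of routine head-and-neck care, an
organ-at-risk model for these glands must learn to predict PET-derived
contours from CT alone. `tubseg` implements that pipeline end to end:

1. **Ground truth** — PET activity is converted to body-weight standard
   uptake values (SUVbw) and thresholded at SUVbw = 1; the largest
   supra-threshold connected component per slice and side is contoured.
2. **Dataset** — CT slices are windowed and min–max normalized, paired
   with per-slice binary masks, and the left-side data is mirrored
   through the mid-sagittal plane and pooled with the right-side data,
   doubling the effective training set for one combined model.
3. **Model** — a 2D MultiResUNet trained with binary cross-entropy and
   Adam (batch size one).
4. **Post-processing** — sigmoid probabilities, a validation-tuned
   binarization threshold, interpolation of single empty "gap" slices,
   Canny-based contour extraction, and DICOM RTSTRUCT export.
5. **Evaluation** — Dice and Jaccard coefficients, the 95th-percentile
   Hausdorff distance, effective gland length and radius, paired
   t-tests, and a patient-level five-fold cross-validation harness.

Because no public PSMA PET/CT cohort with tubarial contours exists, the
package ships a synthetic phantom generator that makes every stage
testable against analytic ground truth.

## The phantom and what it does (not) emulate

`phantom_spec()` describes a registered CT+PET pair containing two
mirror-placed columnar glands: a capped vertical cylinder (default
radius 8.5 mm, axial extent 45 mm, matching reported gland morphology)
continued caudally by a narrower stem (default radius 3 mm over the
caudal 30% — the "narrow columnar" inferior portion). PET voxels inside
the glands sit at SUVbw 4, the background at 0.3, so the SUVbw = 1
threshold sits in a steep step gradient; independent Gaussian noise
(default sd 0.1 SUVbw) leaves the threshold classification essentially
error-free, which is exactly the stated rationale for that threshold
choice on real images. CT is uniform 40 HU soft tissue plus a
configurable gland contrast (default +60 HU, rounded to integer HU as a
scanner would); the default is deliberately *visible* so that
desk-scale training can succeed. Real tubarial glands have **no**
visible CT boundary — phantom results therefore demonstrate that the
pipeline's machinery is correct, not that the clinical task is as easy.
Setting `ct_gland_contrast_hu = 0` reproduces the featureless-CT
regime.

Geometric choices worth knowing:

* The default grid is 96 × 96 × 48 voxels at 1 × 1 × 3 mm — large
  enough to hold a 45 mm gland, small enough for laptop-scale training.
* The gland's axial extent snaps outward to the slice grid, occupying
  `ceiling(L / dz) + 1` contour-bearing slices, so the analytic length
  is recovered exactly by the length metric at default spacing.
* The default lateral offset (18.25 mm) keeps every voxel center off
  the contour polygons, avoiding even-odd boundary ties; truth masks
  are rasterized from the analytic contours, so threshold delineation
  of a noiseless phantom is voxel-exact (Dice 1.0) by construction,
  and the left gland is the bit-exact mirror of the right.
* Cohort variability draws per-patient length (sd 8.5 mm) and radius
  (sd 1.1 mm) from normal distributions around the base spec — the
  reported inter-patient spread of manually delineated glands. Per-
  patient SUV variability is not modelled beyond body weight entering
  the Bq/mL↔SUVbw conversion; nothing in the pipeline consumes
  absolute PET units beyond the threshold.

## Ground-truth delineation

`to_suvbw()` applies the standard definition SUVbw = C·w/A (activity
concentration in Bq/mL, body mass in grams, decay-corrected injected
activity in Bq). The manual "slice by slice around the threshold-defined
perimeter" step is automated as: per axial slice and per lateral half
(the search boxes automate the human's anatomical localization), keep
the largest 8-connected supra-threshold component. Sparse
supra-threshold noise voxels are discarded by that rule. The threshold
perimeter is taken as-is, without manual editing.

## Network and training

The 2D MultiResUNet follows the published architecture: MultiRes blocks
(three chained 3 × 3 convolutions with filter counts ⌊W/6⌋, ⌊W/3⌋,
⌊W/2⌋, W = α·U·2^level, α = 1.67, concatenated and summed with a 1 × 1
shortcut) in place of U-Net's double convolutions, and Res paths
(conv+shortcut chains of depth 4, 3, 2, 1 at levels 1–4) in place of
plain skip connections. Batch normalization and ReLU follow each
convolution; 2 × 2 max-pooling descends, 2 × 2 stride-2 transposed
convolutions ascend; a final 1 × 1 convolution emits a single-channel
logit map. Inputs whose size is not a multiple of 2^levels are
zero-padded and cropped back.

Training follows the stated protocol: 20 epochs, batch size one,
learning rate 0.001, binary cross-entropy with logits, Adam. Weight
initialization (He-uniform), epoch shuffling and the optimizer state
are all fixed by the config seed. With a batch of one, batch
normalization computes statistics over the spatial plane during
training and uses running averages (momentum 0.1) at inference — using
per-slice statistics at inference would amplify noise on near-uniform
background slices into spurious detections. No learning-rate schedule,
weight decay or early stopping is applied.

The numerical core (GEMM-based convolutions via im2col, pooling,
transposed convolutions, connected components) is implemented in
C++ (RcppArmadillo); a small reverse-mode tape in R composes the layers
and is verified against central-difference gradients to better than
1e-4 relative error on every parameter of a two-level network.

## Post-processing

* **Threshold selection** maximizes mean validation Dice over the
  candidate grid {0.05, …, 0.95}; ties break toward 0.5. The threshold
  is tuned per trained model on its validation fold — there is no
  separate test set, mirroring the small-cohort protocol.
* **Binarization** uses `p >= t`, so masks shrink monotonically in `t`.
* **Gap filling** fills an empty slice whose superior and inferior
  neighbours are both non-empty with the per-pixel mean of the
  neighbours thresholded strictly above 0.5 — the intersection of two
  binary neighbours. One pass, no cascading; runs of two or more empty
  slices and volume-boundary slices are untouched. The operation is
  idempotent and never removes voxels.
* **Left-side prediction** mirrors the CT before the network and the
  probability map after it, making the left pipeline exactly
  `mirror ∘ right-pipeline ∘ mirror`.
* **Contours**: Canny edge pixels of each mask slice (Gaussian σ = 1,
  hysteresis 0.1/0.2 on the normalized gradient — any setting detects a
  binary step edge) are grouped into 8-connected components, ordered by
  nearest-neighbour marching, and refined to the sub-pixel 0.5-level
  crossing along the local gradient. That sub-pixel step is what makes
  rasterize ∘ extract ∘ rasterize idempotent and the round trip exact
  on phantom structures; isolated single-pixel components are kept as
  half-voxel outline squares rather than silently dropped. An optional
  largest-3D-component filter exists but is off by default, since the
  reference pipeline describes none.

## Metrics

DSC = 2TP/(2TP + FN + FP); JSC = |A∩B|/|A∪B| (the identity
DSC = 2·JSC/(1 + JSC) is enforced in tests to 1e-12). Both are defined
as 1.0 for two empty masks. HD95 is computed symmetrically on contour
vertex sets (or mask surface voxel centers): the 95th percentile of the
nearest-neighbour distances in each direction, then the maximum; it is
undefined (NA with a warning) when either set is empty. Effective
length is the contoured axial extent; effective radius treats each
slice's contoured area (shoelace formula on the polygons, summed per
slice) as a perfect circle and takes the 90th percentile of the
per-slice radii — close to the maximum but robust to a few noisy
slices. All percentiles use linear interpolation between order
statistics (R's default type-7 convention), fixed here so the P90
radius is reproducible. The paired t-test delegates to `stats::t.test`
and reports an explicit degenerate result when all differences are
equal. Cross-validation statistics are aggregated as fold means, then
mean ± sd across folds.

## Cross-validation

`make_folds()` partitions patients (never slices) into k shuffled folds
whose sizes differ by at most one; 30 patients in 5 folds give the six
validation / 24 training split of the study protocol. Per fold, one
combined model is trained on the pooled training patients, its
threshold tuned on the fold's validation patients, and both glands
predicted and scored per validation patient. A run-time assertion
verifies no validation patient entered training before threshold
selection.

## Desk-scale problem sizes

The package's tests and the acceptance script run the full pipeline at
sizes chosen to finish on a single CPU core while still exercising the
study protocol: the end-to-end experiment trains the pooled model
(base filters 16, 96 × 96 slices, levels 4) on 8 phantoms restricted to
a cranio-caudal band two slices beyond the glands, for 2 epochs
(648 gradient steps), tunes the threshold on 2 held-out phantoms and
evaluates both glands on them; smaller property tests use 32 × 32 or
48 × 48 phantoms and two- or three-level networks. The 20-epoch
protocol itself is exercised on a tiny 8-phantom set. Held-out Dice
≥ 0.8 at this scale demonstrates parameter recovery under visible CT
contrast; it says nothing about performance on real, featureless CT.

## Known limitations

* The phantom's CT contrast makes the learning task far easier than the
  clinical one; the generator is a correctness harness, not a clinical
  simulator (no anatomy, no attenuation/scatter PET physics, no
  PET–CT misregistration).
* PET and CT are assumed pre-registered on a single shared grid;
  resampling between differing grids is out of scope.
* The DICOM codec writes and reads explicit-VR little-endian
  single-frame series and RTSTRUCT objects — the subset this pipeline
  produces and consumes (files verify against pydicom) — not the whole
  standard.
* Exact mirror-equivariance of predictions is not guaranteed by the
  architecture (padding parity); the left-side pipeline is exactly the
  mirrored right-side pipeline, which is the property that matters and
  the one asserted in tests.
* Training determinism holds for a fixed seed, thread count and BLAS;
  floating-point reductions may differ across BLAS builds.
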