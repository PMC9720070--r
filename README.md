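# tubseg

CT-based auto-segmentation of the **tubarial glands** — bilateral
salivary-gland-like tissue in the posterior nasopharynx that lights up
on PSMA PET but has no visible boundary on CT. Radiotherapy planning is
CT-only, so sparing these organs at risk requires a model that predicts
PET-derived contours from CT alone. `tubseg` implements the full
pipeline in R:

* **Ground truth from PET**: conversion of activity concentration to
  body-weight standard uptake values, `SUVbw = C · w / A`, and
  threshold delineation at SUVbw = 1 (largest supra-threshold connected
  component per slice and side).
* **Laterality-pooled training data**: per-slice (CT, binary mask)
  pairs; the left-side data is mirrored through the mid-sagittal plane
  and pooled with the right side, doubling the training set for one
  combined model. Elastic and perspective augmentation are available.
* **2D MultiResUNet** (MultiRes blocks with filter split ⌊W/6⌋, ⌊W/3⌋,
  ⌊W/2⌋, W = 1.67·U·2^level; Res paths of depth 4, 3, 2, 1), trained
  with binary cross-entropy and Adam, batch size one — implemented from
  scratch on RcppArmadillo GEMM kernels with a reverse-mode tape that
  is verified against numerical gradients.
* **Post-processing**: sigmoid, validation-tuned binarization threshold
  (maximum mean Dice over a candidate grid), interpolation of single
  empty gap slices, Canny-based sub-pixel contour extraction, and DICOM
  RTSTRUCT export (explicit-VR little-endian; files verify against
  pydicom).
* **Evaluation**: DSC = 2TP/(2TP+FN+FP), JSC = |A∩B|/|A∪B|, symmetric
  95th-percentile Hausdorff distance, effective gland length (axial
  contour extent) and radius r = P90(√(A/π)), paired t-tests, and a
  patient-level k-fold cross-validation harness (30 patients in 5 folds
  → six validation / 24 training per fold).
* **Synthetic phantoms**: registered CT+PET volumes containing two
  mirror-placed columnar glands (capped cylinder + narrow caudal stem,
  default radius 8.5 mm and length 45 mm) with analytic ground truth,
  so every stage is testable without patient data.

See `vignettes/tubseg-methods.Rmd` for the model, its assumptions,
parameter choices and limitations.

## Worked example

Train the pooled model on eight synthetic patients, tune the threshold
on two held-out patients, and predict both glands:

```r
library(tubseg)

cohort <- generate_cohort(10, phantom_spec(),
                          variability = list(gland_length_mm = 4,
                                             gland_radius_mm = 0.5),
                          seed = 11)
train_pat <- cohort[1:8]; val_pat <- cohort[9:10]

samples <- build_pooled_dataset(train_pat, slice_range = band_slices(2))
cfg <- model_config(epochs = 2, base_filters = 16, seed = 5)
model <- train_multiresunet(build_multiresunet(cfg), samples, cfg,
                            verbose = TRUE)
#> epoch 1/2: mean BCE 0.24659
#> epoch 2/2: mean BCE 0.01884

vp <- list(probs = list(), refs = list())  # validation pairs, both sides
for (pat in val_pat) {
  vp$probs <- c(vp$probs, list(predict_slices(model, pat$ct),
                               predict_slices(model, mirror_lateral(pat$ct))))
  vp$refs <- c(vp$refs, list(rasterize(pat$truth, pat$ct, "Tubarial_R"),
                             mirror_lateral(rasterize(pat$truth, pat$ct,
                                                      "Tubarial_L"))))
}
model <- set_threshold(model, select_threshold(vp$probs, vp$refs))

pat <- val_pat[[1]]
pr <- predict_structure(model, pat$ct, side = "right")
row <- evaluate_structure_pair(pr$structure, pat$truth, pat$ct,
                               "Tubarial_R", "Tubarial_R")
row[c("dsc", "hd95_mm", "length_mm", "truth_length_mm")]
#>         dsc hd95_mm length_mm truth_length_mm
#> 1 0.9494191 7.34912        45              45
```

The held-out Dice (~0.95) and exact length recovery show the pipeline
recovering the phantom's analytic gland parameters end to end; the
mean training BCE falling from 0.247 to 0.019 across the two epochs is
the learning signal. Phantom CT carries a deliberately visible gland
contrast (+60 HU by default), so this demonstrates machinery, not
clinical difficulty — real tubarial glands are invisible on CT.

Predicted structures export as standard RTSTRUCT files:

```r
write_rtstruct(pr$structure, pat$ct, "prediction.dcm")
```

A thin command-line front end wraps the same functions
(`inst/cli/tubseg`): `simulate`, `delineate`, `train`, `predict`,
`evaluate` and `crossval` subcommands.

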