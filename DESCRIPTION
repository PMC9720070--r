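Package: tubseg
Title: CT-Based Auto-Segmentation of the Tubarial Glands with
    PET-Derived Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for delineating the tubarial glands
    (bilateral salivary-gland-like tissue in the posterior nasopharynx)
    on planning CT images. Ground-truth contours are derived from
    registered PSMA PET volumes by body-weight standard-uptake-value
    (SUVbw) thresholding, converted to per-slice binary masks, and used
    to train a 2D MultiResUNet segmentation network with
    laterality-pooled training (left-side data mirrored onto the right).
    Includes a synthetic registered CT+PET phantom cohort generator, a
    DICOM image-series and RTSTRUCT reader/writer, mask post-processing
    (probability thresholding, gap-slice interpolation, Canny-based
    contour extraction), segmentation metrics (Dice, Jaccard, 95th
    percentile Hausdorff distance, effective gland length and radius,
    paired t-tests) and a patient-level k-fold cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
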