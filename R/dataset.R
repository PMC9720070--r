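#' Normalize a CT volume to [0, 1]
#'
#' Clips HU values to a window and rescales linearly to `[0, 1]`. The
#' default soft-tissue window (-100, 300) HU brackets the tissues around
#' the nasopharynx; windowing is idempotent on an already-normalized
#' image with `window = c(0, 1)`.
#'
#' @param v a CT [image_volume].
#' @param window numeric(2): `(low_hu, high_hu)` with `low < high`.
#' @return An [image_volume] with values in `[0, 1]`.
#' @export
normalize_ct <- function(v, window = c(-100, 300)) {
  stop_if_not(inherits(v, "image_volume"), "v must be an image_volume")
  stop_if_not(length(window) == 2 && window[1] < window[2],
              "window must satisfy low < high")
  v$voxels <- pmin(pmax(v$voxels, window[1]), window[2])
  v$voxels <- (v$voxels - window[1]) / (window[2] - window[1])
  v
}

#' Training sample: one CT slice and its binary mask
#'
#' @param image 2D matrix, values in `[0, 1]`.
#' @param mask 2D binary matrix of the same shape.
#' @param patient_id patient identifier.
#' @param slice_index axial slice index within the patient volume.
#' @param pooled_side `"native-right"` or `"mirrored-left"`.
#' @return An object of class `training_sample`.
#' @export
training_sample <- function(image, mask, patient_id, slice_index,
                            pooled_side = c("native-right", "mirrored-left")) {
  pooled_side <- match.arg(pooled_side)
  stop_if_not(is.matrix(image) && identical(dim(image), dim(mask)),
              "image and mask must be matrices of the same shape")
  stop_if_not(min(image) >= 0 && max(image) <= 1,
              "image values must lie in [0, 1]")
  stop_if_not(all(mask %in% c(0, 1)), "mask must be binary")
  structure(list(image = image, mask = mask, patient_id = patient_id,
                 slice_index = as.integer(slice_index),
                 pooled_side = pooled_side),
            class = "training_sample")
}

#' Build the laterality-pooled 2D training set
#'
#' Exploits the bilateral symmetry of the glands to double the
#' effective dataset: for every axial slice of every patient the pooled
#' set contains the native CT slice paired with the right-gland mask,
#' and the laterally mirrored CT slice paired with the mirrored
#' left-gland mask — so one model learns a single (right-side) task.
#' Sample count is exactly `2 * sum(patient slice counts)` (restricted
#' slices excepted, see `slice_range`).
#'
#' @param cohort list of patients, each a list with `ct` (an
#'   [image_volume]) and `truth` (a [structure_set] with a right and a
#'   left structure), plus optionally `patient_id`.
#' @param window HU window passed to [normalize_ct()].
#' @param right,left structure names of the right and left gland;
#'   defaults locate them by laterality tag.
#' @param slice_range optional function(`mask_r`, `mask_l`) returning the
#'   slice indices to keep (e.g. [band_slices()]); default keeps all.
#' @return A list of [training_sample] objects.
#' @export
build_pooled_dataset <- function(cohort, window = c(-100, 300),
                                 right = NULL, left = NULL,
                                 slice_range = NULL) {
  samples <- list()
  for (pi in seq_along(cohort)) {
    pat <- cohort[[pi]]
    pid <- pat$patient_id %||% sprintf("P%03d", pi)
    ct <- normalize_ct(pat$ct, window)
    nms <- structure_names(pat$truth)
    lats <- vapply(pat$truth$structures, `[[`, character(1), "laterality")
    r_nm <- right %||% nms[match("right", lats)]
    l_nm <- left %||% nms[match("left", lats)]
    mask_r <- structure_mask(pat$truth, pat$ct, r_nm, "right", pid)
    mask_l <- structure_mask(pat$truth, pat$ct, l_nm, "left", pid)
    ks <- seq_len(dim(ct$voxels)[3])
    if (!is.null(slice_range)) ks <- slice_range(mask_r, mask_l)
    for (k in ks) {
      samples[[length(samples) + 1L]] <- training_sample(
        ct$voxels[, , k], mask_r[, , k], pid, k, "native-right")
      samples[[length(samples) + 1L]] <- training_sample(
        mirror_slice(ct$voxels[, , k]), mirror_slice(mask_l[, , k]),
        pid, k, "mirrored-left")
    }
  }
  samples
}

# Rasterized mask of one side; a missing structure contributes all-empty
# masks with a warning rather than silence.
structure_mask <- function(truth, grid, nm, side, pid) {
  if (is.na(nm) || is.null(nm)) {
    warning(sprintf("patient %s has no %s structure; using empty masks",
                    pid, side))
    return(array(0L, grid_dim(grid)))
  }
  rasterize(truth, grid, nm)$voxels
}

#' Cranio-caudal band slice restriction
#'
#' Returns a `slice_range` function for [build_pooled_dataset()] that
#' keeps only slices within `margin` slices of any slice where either
#' gland mask is non-empty — the band a clinician would bother
#' segmenting, and a way to keep desk-scale training sets small while
#' still including empty neighbouring slices as negative examples.
#'
#' @param margin slices of context kept on each side of the occupied
#'   band.
#' @return A function usable as `slice_range`.
#' @export
band_slices <- function(margin = 4L) {
  function(mask_r, mask_l) {
    occ <- which(apply(mask_r == 1L, 3, any) | apply(mask_l == 1L, 3, any))
    if (!length(occ)) return(seq_len(dim(mask_r)[3]))
    seq(max(1L, min(occ) - margin),
        min(dim(mask_r)[3], max(occ) + margin))
  }
}

# ---- augmentation ----------------------------------------------------------

# Bilinear sampling of matrix m at fractional (row, col) positions.
bilinear_sample <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  rows <- as.vector(rows); cols <- as.vector(cols)
  r0 <- pmin(pmax(floor(rows), 1), H - 1); c0 <- pmin(pmax(floor(cols), 1), W - 1)
  fr <- pmin(pmax(rows - r0, 0), 1); fc <- pmin(pmax(cols - c0, 0), 1)
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  out <- m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
  out[rows < 1 | rows > H | cols < 1 | cols > W] <- 0
  matrix(out, H, W)
}

# Random smoothed displacement field (Simard-style elastic transform).
elastic_field <- function(H, W, alpha, sigma) {
  k <- gauss_kernel(sigma)
  dx <- sep_convolve(matrix(stats::runif(H * W, -1, 1), H, W), k) * alpha
  dy <- sep_convolve(matrix(stats::runif(H * W, -1, 1), H, W), k) * alpha
  list(dr = dy, dc = dx)
}

# Projective map fitted from 4 point pairs (rows of src/dst: (r, c)).
homography_from_quads <- function(src, dst) {
  A <- matrix(0, 8, 8); bvec <- numeric(8)
  for (i in 1:4) {
    r <- src[i, 1]; c <- src[i, 2]; R <- dst[i, 1]; C <- dst[i, 2]
    A[2 * i - 1, ] <- c(r, c, 1, 0, 0, 0, -r * R, -c * R)
    A[2 * i, ] <- c(0, 0, 0, r, c, 1, -r * C, -c * C)
    bvec[2 * i - 1] <- R; bvec[2 * i] <- C
  }
  h <- solve(A, bvec)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Jointly augment a CT slice and its mask
#'
#' Applies the same random elastic deformation (smoothed random
#' displacement field) and random perspective warp to the image and its
#' mask; the mask is re-binarized at 0.5 after interpolation.
#' Deterministic for a fixed seed; zero magnitudes reproduce the input
#' exactly.
#'
#' @param s a [training_sample].
#' @param seed integer seed.
#' @param elastic_alpha displacement amplitude in pixels (default 30
#'   before smoothing; the smoothed field moves pixels by about 1.5 px).
#' @param elastic_sigma Gaussian smoothing sigma of the displacement
#'   field, in pixels.
#' @param perspective_scale corner jitter of the perspective warp as a
#'   fraction of the image size.
#' @return An augmented [training_sample].
#' @export
augment <- function(s, seed, elastic_alpha = 30, elastic_sigma = 5,
                    perspective_scale = 0.05) {
  stop_if_not(inherits(s, "training_sample"), "s must be a training_sample")
  if (elastic_alpha == 0 && perspective_scale == 0) return(s)
  H <- nrow(s$image); W <- ncol(s$image)
  with_seed(as.integer(seed), {
    base_r <- matrix(rep(seq_len(H), W), H, W)
    base_c <- matrix(rep(seq_len(W), each = H), H, W)
    rows <- base_r; cols <- base_c
    if (perspective_scale > 0) {
      corners <- rbind(c(1, 1), c(1, W), c(H, W), c(H, 1))
      jit <- matrix(stats::runif(8, -perspective_scale, perspective_scale),
                    4, 2) * rep(c(H, W), each = 4)
      Hm <- homography_from_quads(corners, corners + jit)
      den <- Hm[3, 1] * rows + Hm[3, 2] * cols + Hm[3, 3]
      nr <- (Hm[1, 1] * rows + Hm[1, 2] * cols + Hm[1, 3]) / den
      nc <- (Hm[2, 1] * rows + Hm[2, 2] * cols + Hm[2, 3]) / den
      rows <- nr; cols <- nc
    }
    if (elastic_alpha > 0) {
      f <- elastic_field(H, W, elastic_alpha, elastic_sigma)
      rows <- rows + f$dr; cols <- cols + f$dc
    }
    img <- bilinear_sample(s$image, rows, cols)
    msk <- (bilinear_sample(s$mask + 0, rows, cols) >= 0.5) + 0L
  })
  training_sample(pmin(pmax(img, 0), 1), matrix(msk, H, W),
                  s$patient_id, s$slice_index, s$pooled_side)
}
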