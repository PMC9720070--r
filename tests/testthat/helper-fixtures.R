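# Shared fixtures. Small phantom specs keep unit tests fast; the
# full-size default geometry is exercised in the acceptance suite.

# Compact phantom: 48 x 48 voxels at 2 mm in-plane, full gland morphology.
small_spec <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(48L, 48L, 24L),
                                 spacing_mm = c(2, 2, 3)), list(...))
  do.call(phantom_spec, args)
}

# Full-resolution in-plane grid (1 mm), trimmed laterally: contour
# extraction is voxel-exact at this resolution.
exact_spec <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(64L, 64L, 24L),
                                 spacing_mm = c(1, 1, 3)), list(...))
  do.call(phantom_spec, args)
}

# Tiny phantom for training loops: 32 x 32 at 2 mm, short gland.
tiny_spec <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(32L, 32L, 12L),
                                 spacing_mm = c(2, 2, 4),
                                 gland_length_mm = 16, gland_radius_mm = 6,
                                 stem_radius_mm = 2.5,
                                 lateral_offset_mm = 12.25), list(...))
  do.call(phantom_spec, args)
}

# Disc mask volume on a simple grid.
disc_mask <- function(radius_vox, n = 24L, slices = 1L, spacing = c(1, 1, 3)) {
  grid <- image_volume(array(0, c(n, n, slices)),
                       origin_mm = c(-(n - 1) / 2 * spacing[2],
                                     -(n - 1) / 2 * spacing[1], 0),
                       spacing_mm = spacing, modality = "CT")
  ax <- grid_axes(grid)
  sl <- outer(ax$y^2, ax$x^2, `+`) <= (radius_vox * spacing[2])^2
  vox <- array(0L, dim(grid$voxels))
  for (k in seq_len(slices)) vox[, , k] <- as.integer(sl)
  mask_volume(vox, grid)
}

# Plain n x n x k unit-spacing grid.
base_grid <- function(n, slices) {
  image_volume(array(0, c(n, n, slices)), c(0, 0, 0), c(1, 1, 3), "CT")
}

# Random binary mask volume for metric property tests.
random_mask <- function(dim3, p = 0.2, grid = NULL) {
  if (is.null(grid)) {
    grid <- image_volume(array(0, dim3), c(0, 0, 0), c(1, 1, 1), "CT")
  }
  mask_volume(array(as.integer(stats::runif(prod(dim3)) < p), dim3), grid)
}

# Brute-force Dice from first principles (voxel loops kept simple).
dice_oracle <- function(a, b) {
  av <- as.logical(a$voxels); bv <- as.logical(b$voxels)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(av)) {
    if (av[i] && bv[i]) tp <- tp + 1L
    else if (av[i]) fn <- fn + 1L
    else if (bv[i]) fp <- fp + 1L
  }
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fn + fp)
}

jaccard_oracle <- function(a, b) {
  av <- as.logical(a$voxels); bv <- as.logical(b$voxels)
  inter <- sum(av & bv); uni <- sum(av | bv)
  if (uni == 0) return(1)
  inter / uni
}

# Brute-force symmetric HD95 on surface point sets, quadratic in points.
hd95_oracle <- function(a, b, prob = 0.95) {
  pa <- tubseg:::metric_points(a)
  pb <- tubseg:::metric_points(b)
  directed <- function(x, y) {
    d <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      d[i] <- sqrt(min((y[, 1] - x[i, 1])^2 + (y[, 2] - x[i, 2])^2 +
                         (y[, 3] - x[i, 3])^2))
    }
    stats::quantile(d, prob, names = FALSE, type = 7)
  }
  max(directed(pa, pb), directed(pb, pa))
}
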