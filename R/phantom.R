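#' Synthetic phantom specification
#'
#' Parameters of the synthetic registered CT+PET phantom used throughout
#' the package: two mirror-placed columnar glands (a capped vertical
#' cylinder continued caudally by a narrower stem) embedded in a uniform
#' soft-tissue background. Morphology defaults follow the reported
#' tubarial gland statistics (length about 45 mm, radius about 8.5 mm,
#' with a narrow caudal column); PET uptake inside the glands is well
#' above the SUVbw = 1 delineation threshold and the perimeter gradient
#' is a step, so threshold delineation of a noiseless phantom is exact.
#'
#' @param grid_shape integer(3): voxels per axis (rows, columns, slices).
#' @param spacing_mm numeric(3): (row, column, slice) voxel size in mm.
#' @param gland_length_mm target axial gland extent (mm); the realized
#'   extent snaps outward to the slice grid, occupying
#'   `ceiling(length/dz) + 1` contour-bearing slices.
#' @param gland_radius_mm cross-sectional radius of the gland body (mm).
#' @param stem_fraction fraction of the axial extent occupied by the
#'   narrow caudal stem.
#' @param stem_radius_mm stem cross-sectional radius (mm); must be
#'   smaller than `gland_radius_mm`.
#' @param lateral_offset_mm distance of each gland axis from the
#'   mid-sagittal plane (mm). The default is chosen off the voxel-center
#'   lattice so no center falls exactly on a contour edge.
#' @param suv_inside mean SUVbw inside the glands (must exceed 1).
#' @param suv_background mean SUVbw outside (must be below 1).
#' @param noise_sd additive Gaussian noise scale: PET noise sd in SUVbw
#'   units; CT noise sd is `20 * noise_sd` HU (then rounded to integer
#'   HU, as a scanner would quantize).
#' @param ct_gland_contrast_hu HU offset of gland tissue over the 40 HU
#'   soft-tissue background. The default is visible so that desk-scale
#'   training can succeed; set 0 for CT-realism experiments (tubarial
#'   boundaries are not visible on real CT).
#' @param body_weight_kg,injected_activity_MBq patient parameters used
#'   when the PET volume is expressed in activity units.
#' @param pet_units `"SUVbw"` (default) or `"Bq/mL"`; with `"Bq/mL"` the
#'   PET voxels are scaled so that [to_suvbw()] recovers the SUVbw field.
#' @param seed integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 48L),
                         spacing_mm = c(1, 1, 3),
                         gland_length_mm = 45,
                         gland_radius_mm = 8.5,
                         stem_fraction = 0.3,
                         stem_radius_mm = 3,
                         lateral_offset_mm = 18.25,
                         suv_inside = 4,
                         suv_background = 0.3,
                         noise_sd = 0.1,
                         ct_gland_contrast_hu = 60,
                         body_weight_kg = 90,
                         injected_activity_MBq = 350,
                         pet_units = c("SUVbw", "Bq/mL"),
                         seed = 1L) {
  pet_units <- match.arg(pet_units)
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               gland_length_mm = gland_length_mm,
               gland_radius_mm = gland_radius_mm,
               stem_fraction = stem_fraction,
               stem_radius_mm = stem_radius_mm,
               lateral_offset_mm = lateral_offset_mm,
               suv_inside = suv_inside,
               suv_background = suv_background,
               noise_sd = noise_sd,
               ct_gland_contrast_hu = ct_gland_contrast_hu,
               body_weight_kg = body_weight_kg,
               injected_activity_MBq = injected_activity_MBq,
               pet_units = pet_units,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stop_if_not(length(spec$grid_shape) == 3L && all(spec$grid_shape >= 2L),
              "grid_shape must be three dimensions of at least 2 voxels")
  stop_if_not(all(spec$spacing_mm > 0), "spacing_mm must be positive")
  stop_if_not(spec$gland_length_mm > 0, "gland_length_mm must be positive")
  stop_if_not(spec$gland_radius_mm > spec$stem_radius_mm &&
                spec$stem_radius_mm > 0,
              "need gland_radius_mm > stem_radius_mm > 0")
  stop_if_not(spec$stem_fraction >= 0 && spec$stem_fraction < 1,
              "stem_fraction must lie in [0, 1)")
  stop_if_not(spec$suv_inside > 1 && spec$suv_background < 1 &&
                spec$suv_background >= 0,
              "need suv_inside > 1 > suv_background >= 0")
  stop_if_not(spec$noise_sd >= 0, "noise_sd must be non-negative")
  stop_if_not(spec$body_weight_kg > 0 && spec$injected_activity_MBq > 0,
              "body weight and injected activity must be positive")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> grid %d x %d x %d @ %.3g x %.3g x %.3g mm; ",
                     "gland L = %.1f mm, r = %.2f mm (stem r = %.2f, frac %.2f)\n"),
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$gland_length_mm, x$gland_radius_mm, x$stem_radius_mm,
              x$stem_fraction))
  cat(sprintf("  SUVbw %.2f in / %.2f out, noise sd %.3g, CT contrast %+.0f HU, seed %d\n",
              x$suv_inside, x$suv_background, x$noise_sd,
              x$ct_gland_contrast_hu, x$seed))
  invisible(x)
}

# Circle contour as a closed polygon (64 vertices).
circle_contour <- function(cx, cy, r, z, n = 64L) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  list(z = z, xy = cbind(cx + r * cos(th), cy + r * sin(th)))
}

# Mirror a contour through the mid-sagittal plane by exact x negation.
mirror_contour <- function(ct) {
  list(z = ct$z, xy = cbind(-ct$xy[, 1], ct$xy[, 2]))
}

# Analytic truth contours for the right gland; left is its exact mirror.
phantom_truth <- function(spec, grid) {
  d <- spec$grid_shape
  dz <- spec$spacing_mm[3]
  n_slices <- as.integer(ceiling(spec$gland_length_mm / dz)) + 1L
  stop_if_not(n_slices <= d[3],
              "grid too small: gland needs %d slices but grid has %d",
              n_slices, d[3])
  ax <- grid_axes(grid)
  half_x <- max(abs(ax$x)); half_y <- max(abs(ax$y))
  stop_if_not(spec$lateral_offset_mm + spec$gland_radius_mm <= half_x &&
                spec$gland_radius_mm <= half_y,
              "grid too small: gland of radius %.2f mm at offset %.2f mm would be clipped",
              spec$gland_radius_mm, spec$lateral_offset_mm)
  k0 <- (d[3] - n_slices) %/% 2L + 1L
  ks <- k0:(k0 + n_slices - 1L)           # caudal (low z) slices first
  n_stem <- as.integer(floor(spec$stem_fraction * n_slices))
  radii <- c(rep(spec$stem_radius_mm, n_stem),
             rep(spec$gland_radius_mm, n_slices - n_stem))
  right <- lapply(seq_along(ks), function(i) {
    circle_contour(-spec$lateral_offset_mm, 0, radii[i], ax$z[ks[i]])
  })
  left <- lapply(right, mirror_contour)
  structure_set(list(
    Tubarial_R = list(contours = right, laterality = "right"),
    Tubarial_L = list(contours = left, laterality = "left")
  ))
}

#' Generate a synthetic registered CT+PET phantom
#'
#' Builds a CT volume (uniform 40 HU soft tissue plus a configurable
#' gland contrast), a registered PET volume (SUVbw `suv_inside` inside
#' the glands, `suv_background` outside, optional Gaussian noise) and the
#' analytic ground-truth structure set with a `Tubarial_R` and a
#' `Tubarial_L` structure. The PET field is painted from the rasterized
#' truth contours, so threshold delineation of a noiseless phantom
#' recovers the truth exactly, and the left gland is the voxel-exact
#' lateral mirror of the right gland. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `ct`, `pet` (both [image_volume]),
#'   `truth` (a [structure_set]) and `suv_params` (a [suv_params] object
#'   describing the simulated patient).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  origin <- c(-(d[2] - 1) / 2 * sp[2], -(d[1] - 1) / 2 * sp[1], 0)
  geom <- image_volume(array(0, d), origin, sp, "CT")
  truth <- phantom_truth(spec, geom)
  mask_r <- rasterize(truth, geom, "Tubarial_R")$voxels
  mask_l <- rasterize(truth, geom, "Tubarial_L")$voxels
  mask <- mask_r | mask_l

  with_seed(spec$seed, {
    suv <- spec$suv_background +
      (spec$suv_inside - spec$suv_background) * mask
    hu <- 40 + spec$ct_gland_contrast_hu * mask
    if (spec$noise_sd > 0) {
      suv <- suv + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
      suv[suv < 0] <- 0
      hu <- hu + array(stats::rnorm(prod(d), sd = 20 * spec$noise_sd), d)
    }
    hu <- round(hu)
  })

  p <- suv_params(body_weight_kg = spec$body_weight_kg,
                  injected_activity_Bq = spec$injected_activity_MBq * 1e6)
  pet_vox <- if (spec$pet_units == "Bq/mL") {
    suv * p$injected_activity_Bq / (p$body_weight_kg * 1000)
  } else suv
  list(ct = image_volume(array(hu, d), origin, sp, "CT"),
       pet = image_volume(array(pet_vox, d), origin, sp, "PET"),
       truth = truth,
       suv_params = p)
}

#' Generate a cohort of phantoms with per-patient variability
#'
#' Draws per-patient gland morphology (and body weight) around a base
#' specification from independent normal distributions, clamped to
#' geometrically valid ranges, and generates one phantom per patient.
#' Reproducible for a fixed `seed`; patient identifiers are unique.
#'
#' @param n number of patients (>= 1).
#' @param base_spec a [phantom_spec] providing the cohort means.
#' @param variability named list of per-field normal spreads (sd) applied
#'   around `base_spec`; supported fields are `gland_length_mm`
#'   (default 8.5), `gland_radius_mm` (default 1.1) and `body_weight_kg`
#'   (default 0). Use `variability = list()` with the defaults overridden
#'   to 0 for geometrically identical patients.
#' @param seed integer seed for the cohort draw.
#' @return A list of length `n`; each element is the [generate_phantom()]
#'   result plus `patient_id` and `spec` (the realized per-patient spec).
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            variability = list(), seed = 1L) {
  stop_if_not(is_count(n) && n >= 1, "n must be a positive integer")
  spread <- list(gland_length_mm = 8.5, gland_radius_mm = 1.1,
                 body_weight_kg = 0)
  stop_if_not(all(names(variability) %in% names(spread)),
              "unsupported variability field(s): %s",
              paste(setdiff(names(variability), names(spread)), collapse = ", "))
  spread[names(variability)] <- variability

  draws <- with_seed(as.integer(seed), {
    list(length = stats::rnorm(n, base_spec$gland_length_mm,
                               spread$gland_length_mm),
         radius = stats::rnorm(n, base_spec$gland_radius_mm,
                               spread$gland_radius_mm),
         weight = stats::rnorm(n, base_spec$body_weight_kg,
                               spread$body_weight_kg),
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  dz <- base_spec$spacing_mm[3]
  lapply(seq_len(n), function(i) {
    spec <- base_spec
    spec$gland_length_mm <- max(draws$length[i], 2 * dz)
    spec$gland_radius_mm <- max(draws$radius[i], base_spec$stem_radius_mm + 0.5)
    spec$body_weight_kg <- max(draws$weight[i], 30)
    spec$seed <- draws$seeds[i]
    out <- generate_phantom(spec)
    out$patient_id <- sprintf("P%03d", i)
    out$spec <- spec
    out
  })
}
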