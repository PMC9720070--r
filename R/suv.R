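#' SUV normalization parameters
#'
#' Patient parameters for converting PET activity concentration to
#' body-weight standard uptake values, plus the delineation threshold.
#' Injected activity is assumed already decay-corrected to scan time.
#'
#' @param body_weight_kg patient mass in kg (> 0).
#' @param injected_activity_Bq decay-corrected injected activity in Bq
#'   (> 0).
#' @param threshold SUVbw lower bound defining gland tissue; default 1.
#' @return An object of class `suv_params`.
#' @export
suv_params <- function(body_weight_kg, injected_activity_Bq, threshold = 1.0) {
  stop_if_not(is.numeric(body_weight_kg) && body_weight_kg > 0,
              "body_weight_kg must be positive")
  stop_if_not(is.numeric(injected_activity_Bq) && injected_activity_Bq > 0,
              "injected_activity_Bq must be positive")
  stop_if_not(is.numeric(threshold) && threshold > 0,
              "threshold must be positive")
  structure(list(body_weight_kg = body_weight_kg,
                 injected_activity_Bq = injected_activity_Bq,
                 threshold = threshold),
            class = "suv_params")
}

#' @export
print.suv_params <- function(x, ...) {
  cat(sprintf("<suv_params> weight %.1f kg, activity %.1f MBq, SUVbw threshold %.2f\n",
              x$body_weight_kg, x$injected_activity_Bq / 1e6, x$threshold))
  invisible(x)
}

#' Convert PET activity concentration to SUVbw
#'
#' Standard body-weight SUV: each voxel's activity concentration
#' (Bq/mL) is scaled by body mass in grams over injected activity,
#' `SUVbw = C * (w * 1000) / A`, so a voxel at 5000 Bq/mL in a 70 kg
#' patient injected with 350 MBq maps to SUVbw = 1 exactly. Geometry and
#' modality are unchanged.
#'
#' @param pet a PET [image_volume] in Bq/mL.
#' @param p an [suv_params] object.
#' @return A PET [image_volume] in SUVbw units.
#' @export
to_suvbw <- function(pet, p) {
  stop_if_not(inherits(pet, "image_volume") && pet$modality == "PET",
              "pet must be a PET image_volume")
  stop_if_not(inherits(p, "suv_params"), "p must be an suv_params object")
  pet$voxels <- pet$voxels * (p$body_weight_kg * 1000) / p$injected_activity_Bq
  pet
}

# Default per-gland search regions: each lateral half of the volume.
default_roi_boxes <- function(suv) {
  ax <- grid_axes(suv)
  list(right = list(x = c(-Inf, 0), y = c(-Inf, Inf), z = c(-Inf, Inf)),
       left = list(x = c(0, Inf), y = c(-Inf, Inf), z = c(-Inf, Inf)))
}

#' Threshold-based delineation of the tubarial glands
#'
#' Reproduces the PET ground-truth delineation path: voxels at or above
#' the SUVbw threshold are candidate gland tissue; within each per-side
#' search region (which automates the anatomical localization a human
#' delineator performs), the largest supra-threshold 8-connected
#' component of every axial slice is retained, and the resulting mask is
#' converted to closed contours via [extract_contours()]. Sparse
#' supra-threshold noise outside the glands is discarded by the
#' largest-component rule.
#'
#' @param suv a PET [image_volume] already in SUVbw units.
#' @param p an [suv_params] carrying the threshold.
#' @param roi_boxes named list (`right`, `left`) of per-gland search
#'   boxes, each a list of `x`, `y`, `z` ranges in patient mm. Default:
#'   the two lateral halves of the volume.
#' @param names structure names for the right and left gland.
#' @return A [structure_set] with a right and a left structure; a side
#'   with no supra-threshold voxels yields an empty structure with a
#'   warning.
#' @export
delineate_by_threshold <- function(suv, p, roi_boxes = NULL,
                                   names = c("Tubarial_R", "Tubarial_L")) {
  stop_if_not(inherits(suv, "image_volume") && suv$modality == "PET",
              "suv must be a PET image_volume")
  stop_if_not(inherits(p, "suv_params"), "p must be an suv_params object")
  roi_boxes <- roi_boxes %||% default_roi_boxes(suv)
  stop_if_not(all(c("right", "left") %in% base::names(roi_boxes)),
              "roi_boxes must have 'right' and 'left' entries")
  ax <- grid_axes(suv)
  d <- grid_dim(suv)
  structures <- list()
  for (side in c("right", "left")) {
    box <- roi_boxes[[side]]
    in_x <- ax$x >= box$x[1] & ax$x <= box$x[2]
    in_y <- ax$y >= box$y[1] & ax$y <= box$y[2]
    in_z <- ax$z >= box$z[1] & ax$z <= box$z[2]
    mask <- array(0L, d)
    for (k in which(in_z)) {
      sl <- (suv$voxels[, , k] >= p$threshold) & outer(in_y, in_x, `&`)
      if (!any(sl)) next
      lab <- cc_label(matrix(as.integer(sl), d[1]), 8L)
      sizes <- tabulate(lab[lab > 0])
      mask[, , k] <- as.integer(lab == which.max(sizes))
    }
    if (!any(mask == 1L)) {
      warning(sprintf("no supra-threshold voxels in the %s search region", side))
    }
    nm <- if (side == "right") names[1] else names[2]
    ss <- extract_contours(mask_volume(mask, suv), name = nm,
                           laterality = side)
    structures[[nm]] <- ss$structures[[nm]]
  }
  structure_set(structures)
}
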