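#' Image volume container
#'
#' A 3D scalar grid (CT in Hounsfield units, or PET in activity
#' concentration / SUVbw) together with its patient-space geometry. The
#' array is indexed `[row, column, slice]` where rows run along the
#' anterior--posterior (y) axis, columns along the patient right--left (x)
#' axis and slices along the cranio--caudal (z) axis, following the DICOM
#' LPS convention: voxel `[i, j, k]` has its center at
#' `(origin_x + (j-1)*dx, origin_y + (i-1)*dy, slice_positions[k])`.
#'
#' @param voxels 3D numeric array, dim `(rows, cols, slices)`.
#' @param origin_mm numeric(3): patient coordinates (x, y, z) of the center
#'   of voxel `[1, 1, 1]`.
#' @param spacing_mm numeric(3): (row, column, slice) voxel sizes in mm,
#'   all strictly positive.
#' @param modality `"CT"` or `"PET"`.
#' @param slice_positions_mm optional numeric vector of per-slice axial
#'   coordinates; defaults to a uniform grid starting at `origin_mm[3]`.
#'   Must be strictly monotonic.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, origin_mm, spacing_mm,
                         modality = c("CT", "PET"),
                         slice_positions_mm = NULL) {
  modality <- match.arg(modality)
  stop_if_not(is.array(voxels) && length(dim(voxels)) == 3L,
              "voxels must be a 3D array")
  stop_if_not(length(origin_mm) == 3L && all(is.finite(origin_mm)),
              "origin_mm must be numeric(3)")
  stop_if_not(length(spacing_mm) == 3L && all(spacing_mm > 0),
              "spacing_mm must be strictly positive numeric(3)")
  ns <- dim(voxels)[3]
  if (is.null(slice_positions_mm)) {
    slice_positions_mm <- origin_mm[3] + (seq_len(ns) - 1) * spacing_mm[3]
  }
  stop_if_not(length(slice_positions_mm) == ns,
              "slice_positions_mm length must equal slice count")
  d <- diff(slice_positions_mm)
  stop_if_not(ns == 1L || all(d > 0) || all(d < 0),
              "slice_positions_mm must be strictly monotonic")
  structure(list(voxels = voxels,
                 origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm),
                 slice_positions_mm = as.numeric(slice_positions_mm),
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; values in [%.3g, %.3g]\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask volume aligned to a reference grid
#'
#' @param voxels 3D array coercible to 0/1, same shape as the reference.
#' @param grid an [image_volume] (or another `mask_volume`) supplying the
#'   geometry the mask is aligned to.
#' @return An object of class `mask_volume` carrying the grid geometry.
#' @export
mask_volume <- function(voxels, grid) {
  stop_if_not(is.array(voxels) && length(dim(voxels)) == 3L,
              "voxels must be a 3D array")
  stop_if_not(all(voxels %in% c(0, 1)) || is.logical(voxels),
              "mask voxels must be binary")
  stop_if_not(identical(dim(voxels), grid_dim(grid)),
              "mask shape must match its reference grid")
  mode(voxels) <- "integer"
  structure(list(voxels = voxels,
                 origin_mm = grid$origin_mm,
                 spacing_mm = grid$spacing_mm,
                 slice_positions_mm = grid$slice_positions_mm),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask_volume> %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

grid_dim <- function(g) dim(g$voxels)

# TRUE if two volumes share a voxel grid (to tol mm).
same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    max(abs(a$origin_mm - b$origin_mm)) <= tol &&
    max(abs(a$spacing_mm - b$spacing_mm)) <= tol &&
    max(abs(a$slice_positions_mm - b$slice_positions_mm)) <= tol
}

# Voxel-center coordinate axes of a grid (mm).
grid_axes <- function(g) {
  d <- grid_dim(g)
  list(x = g$origin_mm[1] + (seq_len(d[2]) - 1) * g$spacing_mm[2],
       y = g$origin_mm[2] + (seq_len(d[1]) - 1) * g$spacing_mm[1],
       z = g$slice_positions_mm)
}

#' Structure set: named planar contours in patient coordinates
#'
#' The in-memory analogue of a DICOM RTSTRUCT: a named set of regions,
#' each stored as a list of closed planar polygons. Every contour is a
#' list with elements `z` (slice coordinate, mm) and `xy` (an n x 2 matrix
#' of vertices in patient mm, n >= 3, implicitly closed).
#'
#' @param structures named list; each element is a list with `contours`
#'   (possibly empty list of contours as above) and `laterality` (one of
#'   `"right"`, `"left"`, `"none"`).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(structures) {
  stop_if_not(is.list(structures) && !is.null(names(structures)) &&
                all(nzchar(names(structures))),
              "structures must be a named list")
  for (nm in names(structures)) {
    s <- structures[[nm]]
    s$laterality <- s$laterality %||% "none"
    stop_if_not(s$laterality %in% c("right", "left", "none"),
                "invalid laterality for structure '%s'", nm)
    s$contours <- s$contours %||% list()
    for (ct in s$contours) {
      stop_if_not(is.matrix(ct$xy) && ncol(ct$xy) == 2L && nrow(ct$xy) >= 3L,
                  "contours of '%s' must be n x 2 matrices with n >= 3", nm)
      stop_if_not(length(ct$z) == 1L && is.finite(ct$z),
                  "each contour of '%s' must lie on one slice plane", nm)
    }
    structures[[nm]] <- s
  }
  structure(list(structures = structures), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structure(s)\n", length(x$structures)))
  for (nm in names(x$structures)) {
    s <- x$structures[[nm]]
    nz <- length(unique(vapply(s$contours, `[[`, numeric(1), "z")))
    cat(sprintf("  %-14s %-5s  %d contour(s) on %d slice(s)\n",
                nm, s$laterality, length(s$contours), nz))
  }
  invisible(x)
}

#' @rdname structure_set
#' @param x a `structure_set`.
#' @export
structure_names <- function(x) names(x$structures)

# ---- point-in-polygon (even-odd) ------------------------------------------

# Even-odd (crossing-number) test of grid centers against one polygon.
# xs, ys: center coordinate axes; poly: n x 2 (x, y) mm. Returns a
# logical matrix (length(ys) x length(xs)) matching [row, col] indexing.
points_in_polygon <- function(xs, ys, poly) {
  nx <- length(xs); ny <- length(ys)
  px <- matrix(rep(xs, each = ny), ny, nx)
  py <- matrix(rep(ys, times = nx), ny, nx)
  inside <- matrix(FALSE, ny, nx)
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next
    crosses <- ((y1[e] > py) != (y2[e] > py)) &
      (px < x1[e] + (py - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e]))
    inside <- xor(inside, crosses)
  }
  inside
}

#' Rasterize structure contours onto an image grid
#'
#' A voxel is set to 1 iff its center lies inside the slice's polygon(s)
#' under the even-odd rule; polygons on the same slice combine by
#' even-odd parity (so disjoint blobs union and nested contours form
#' holes). Slices bearing no contour are all zero. Contours must sit on a
#' grid slice plane (within half a slice spacing); contours reaching
#' outside the grid are clipped with a warning.
#'
#' @param s a [structure_set].
#' @param grid an [image_volume] providing the target geometry.
#' @param structure name of the structure to rasterize; `NULL` (default)
#'   rasterizes the union of all structures.
#' @return A [mask_volume] on `grid`.
#' @export
rasterize <- function(s, grid, structure = NULL) {
  stop_if_not(inherits(s, "structure_set"), "s must be a structure_set")
  nms <- if (is.null(structure)) structure_names(s) else structure
  stop_if_not(all(nms %in% structure_names(s)),
              "unknown structure name(s): %s",
              paste(setdiff(nms, structure_names(s)), collapse = ", "))
  d <- grid_dim(grid)
  ax <- grid_axes(grid)
  dz <- if (d[3] > 1) min(abs(diff(ax$z))) else grid$spacing_mm[3]
  out <- array(0L, d)
  clipped <- FALSE
  for (nm in nms) {
    m <- array(FALSE, d)
    for (ct in s$structures[[nm]]$contours) {
      k <- which.min(abs(ax$z - ct$z))
      stop_if_not(abs(ax$z[k] - ct$z) <= dz / 2 + 1e-9,
                  "contour at z = %.3f mm matches no grid slice", ct$z)
      if (min(ct$xy[, 1]) < min(ax$x) - 1e-9 ||
          max(ct$xy[, 1]) > max(ax$x) + 1e-9 ||
          min(ct$xy[, 2]) < min(ax$y) - 1e-9 ||
          max(ct$xy[, 2]) > max(ax$y) + 1e-9) clipped <- TRUE
      m[, , k] <- xor(m[, , k], points_in_polygon(ax$x, ax$y, ct$xy))
    }
    out <- out | m
  }
  if (clipped) warning("contour extends outside the grid; clipped")
  mask_volume(array(as.integer(out), d), grid)
}

#' Mirror a volume about the mid-sagittal plane
#'
#' Reverses voxel columns along the patient left--right axis, reflecting
#' the image content through the grid's lateral midplane ("flipping about
#' the posterior--anterior axis"). The grid geometry is its own mirror
#' frame, so geometry is unchanged and the operation is an exact
#' involution: `mirror_lateral(mirror_lateral(x))` is `x`, bit for bit.
#' Column `j` maps to column `ncol - j + 1`.
#'
#' @param x an [image_volume] or [mask_volume].
#' @return An object of the same class as `x`.
#' @export
mirror_lateral <- function(x) {
  stop_if_not(inherits(x, "image_volume") || inherits(x, "mask_volume"),
              "x must be an image_volume or mask_volume")
  x$voxels <- x$voxels[, rev(seq_len(dim(x$voxels)[2])), , drop = FALSE]
  x
}

# Mirror a single 2D slice (rows x cols) laterally.
mirror_slice <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
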