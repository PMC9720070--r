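#' Dice similarity coefficient of two masks
#'
#' `DSC = 2TP / (2TP + FN + FP)` over voxels on a shared grid. Two empty
#' masks are defined to agree perfectly (DSC = 1), the common convention
#' for a degenerate case the formula leaves 0/0.
#'
#' @param a,b [mask_volume] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_mask_pair(a, b)
  tp <- sum(a$voxels == 1L & b$voxels == 1L)
  denom <- 2 * tp + sum(a$voxels == 1L & b$voxels == 0L) +
    sum(a$voxels == 0L & b$voxels == 1L)
  if (denom == 0) return(1.0)
  2 * tp / denom
}

#' Jaccard similarity coefficient of two masks
#'
#' `JSC = |A intersect B| / |A union B|`; two empty masks give 1.
#'
#' @inheritParams dice
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  check_mask_pair(a, b)
  inter <- sum(a$voxels == 1L & b$voxels == 1L)
  uni <- sum(a$voxels == 1L | b$voxels == 1L)
  if (uni == 0) return(1.0)
  inter / uni
}

check_mask_pair <- function(a, b) {
  stop_if_not(inherits(a, "mask_volume") && inherits(b, "mask_volume"),
              "a and b must be mask_volume objects")
  stop_if_not(same_grid(a, b), "masks must share a voxel grid")
}

# Point set (patient mm) of a structure's contour vertices, or of a
# mask's surface voxels (foreground voxels with a 6-neighbour background).
metric_points <- function(x, structure = NULL) {
  if (inherits(x, "structure_set")) {
    nms <- structure %||% structure_names(x)
    pts <- list()
    for (nm in nms) for (ct in x$structures[[nm]]$contours) {
      pts[[length(pts) + 1L]] <- cbind(ct$xy, ct$z)
    }
    if (!length(pts)) return(matrix(numeric(0), 0, 3))
    do.call(rbind, pts)
  } else if (inherits(x, "mask_volume")) {
    v <- x$voxels
    d <- dim(v)
    pad <- array(0L, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
    interior <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] &
      pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] &
      pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1), drop = FALSE] &
      pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1), drop = FALSE] &
      pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3], drop = FALSE] &
      pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2), drop = FALSE]
    idx <- which(v == 1L & !interior, arr.ind = TRUE)
    if (!nrow(idx)) return(matrix(numeric(0), 0, 3))
    ax <- grid_axes(x)
    cbind(ax$x[idx[, 2]], ax$y[idx[, 1]], ax$z[idx[, 3]])
  } else stop("expected a structure_set or mask_volume", call. = FALSE)
}

# Directed nearest-neighbour distances from each row of a to b (mm),
# chunked to bound memory.
nn_distances <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  bt <- t(b)
  b2 <- colSums(bt^2)
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    ax <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ax^2), b2, `+`) - 2 * ax %*% bt
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95th percentile Hausdorff distance
#'
#' Symmetric HD95 between two point sets in patient mm: the 95th
#' percentile of the nearest-neighbour distances is taken in each
#' direction (robustifying the classical maximin Hausdorff distance
#' against a small subset of outliers) and the larger of the two is
#' returned. Structure sets contribute their contour vertices; mask
#' volumes contribute their surface voxel centers.
#'
#' @param a,b [structure_set] or [mask_volume] objects (both non-empty).
#' @param structure_a,structure_b optional structure name(s) restricting
#'   which structures of a structure set contribute points.
#' @param prob percentile level, default 0.95.
#' @return Distance in mm, or `NA` (with a warning) if either set is
#'   empty.
#' @export
hd95 <- function(a, b, structure_a = NULL, structure_b = NULL, prob = 0.95) {
  pa <- metric_points(a, structure_a)
  pb <- metric_points(b, structure_b)
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    warning("hd95 undefined for an empty point set; returning NA")
    return(NA_real_)
  }
  max(stats::quantile(nn_distances(pa, pb), prob, names = FALSE, type = 7),
      stats::quantile(nn_distances(pb, pa), prob, names = FALSE, type = 7))
}

contour_slice_positions <- function(s, structure) {
  vapply(s$structures[[structure]]$contours, `[[`, numeric(1), "z")
}

#' Effective axial gland length
#'
#' Axial extent of a structure: the difference between the highest and
#' lowest slice positions bearing contours.
#'
#' @param s a [structure_set].
#' @param structure structure name; defaults to the only structure.
#' @return Length in mm (0 for a single-slice structure).
#' @export
effective_length <- function(s, structure = NULL) {
  stop_if_not(inherits(s, "structure_set"), "s must be a structure_set")
  structure <- structure %||% single_structure_name(s)
  z <- contour_slice_positions(s, structure)
  stop_if_not(length(z) > 0, "structure '%s' has no contours", structure)
  max(z) - min(z)
}

single_structure_name <- function(s) {
  stop_if_not(length(s$structures) == 1L,
              "specify a structure name (set has %d)", length(s$structures))
  structure_names(s)
}

# Shoelace polygon area (mm^2).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Effective gland radius (90th percentile slice radius)
#'
#' Treats the contoured area of each slice as a perfect circle: per
#' slice, polygon areas (shoelace formula) are summed and converted to
#' an equivalent-circle radius `sqrt(A / pi)`; the 90th percentile of
#' the per-slice radii is returned, computed by linear interpolation
#' between order statistics (R's default type-7 quantile). The 90th
#' percentile is close to the maximum slice radius but robust to noise
#' in a handful of slices.
#'
#' @inheritParams effective_length
#' @param prob percentile level, default 0.9.
#' @return Radius in mm.
#' @export
effective_radius <- function(s, structure = NULL, prob = 0.9) {
  stop_if_not(inherits(s, "structure_set"), "s must be a structure_set")
  structure <- structure %||% single_structure_name(s)
  cts <- s$structures[[structure]]$contours
  stop_if_not(length(cts) > 0, "structure '%s' has no contours", structure)
  z <- vapply(cts, `[[`, numeric(1), "z")
  areas <- vapply(cts, function(ct) polygon_area(ct$xy), numeric(1))
  slice_area <- tapply(areas, z, sum)
  radii <- sqrt(as.numeric(slice_area) / pi)
  stats::quantile(radii, prob, names = FALSE, type = 7)
}

#' Paired t-test on matched gland measurements
#'
#' Classical two-sided paired t-test on the differences `x - y`
#' (delegating to [stats::t.test()]), with an explicit degenerate result
#' when all differences are identical (zero-variance differences leave
#' the t statistic undefined).
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @return A list with `t`, `p`, `df`, `mean_difference` and
#'   `degenerate` (TRUE when the difference variance is 0, in which case
#'   `t` and `p` are `NA`).
#' @export
paired_t_test <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y must be paired")
  stop_if_not(length(x) >= 2, "need at least two pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = mean(d),
       degenerate = FALSE)
}

#' Aggregate per-patient metrics over cross-validation folds
#'
#' Computes fold-level means of each metric, then the mean and standard
#' deviation across folds (the reporting convention of fold-averaged
#' cross-validation statistics).
#'
#' @param per_patient data.frame with one row per evaluated structure /
#'   patient, containing numeric metric columns.
#' @param folds integer/factor vector assigning each row to a fold.
#' @param metrics which columns to aggregate; defaults to all numeric
#'   columns.
#' @return A list with `fold_means` (data.frame, one row per fold) and
#'   `summary` (data.frame with cross-fold `mean` and `sd` per metric).
#' @export
aggregate_folds <- function(per_patient, folds, metrics = NULL) {
  stop_if_not(nrow(per_patient) == length(folds),
              "folds must assign every row")
  stop_if_not(!anyNA(folds), "fold assignment must be complete")
  metrics <- metrics %||%
    names(per_patient)[vapply(per_patient, is.numeric, logical(1))]
  fold_ids <- sort(unique(folds))
  fold_means <- do.call(rbind, lapply(fold_ids, function(f) {
    rows <- per_patient[folds == f, metrics, drop = FALSE]
    stop_if_not(nrow(rows) > 0, "fold %s is empty", f)
    cbind(data.frame(fold = f),
          as.data.frame(lapply(rows, mean, na.rm = TRUE)))
  }))
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(fold_means[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(fold_means[[m]]), numeric(1)),
    row.names = NULL)
  list(fold_means = fold_means, summary = summary)
}
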