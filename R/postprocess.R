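#' Select the binarization threshold on a validation fold
#'
#' The network's sigmoid output is binarized at a threshold tuned per
#' trained model: each candidate is scored by the mean validation Dice
#' coefficient between the thresholded probability volumes and the
#' reference masks, and the best candidate is returned. Ties are broken
#' toward 0.5 (then toward the smaller candidate), so a degenerate
#' validation set that scores all candidates equally yields 0.5.
#'
#' @param prob_volumes list of probability [image_volume]s (or plain
#'   arrays) from [predict_slices()].
#' @param reference_masks list of [mask_volume]s paired with
#'   `prob_volumes`.
#' @param candidates candidate grid in (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @return The selected threshold (scalar).
#' @export
select_threshold <- function(prob_volumes, reference_masks,
                             candidates = seq(0.05, 0.95, by = 0.05)) {
  stop_if_not(length(prob_volumes) > 0, "validation set is empty")
  stop_if_not(length(prob_volumes) == length(reference_masks),
              "probability and reference lists must pair up")
  stop_if_not(all(candidates > 0 & candidates < 1),
              "candidates must lie in (0, 1)")
  scores <- vapply(candidates, function(t) {
    mean(vapply(seq_along(prob_volumes), function(i) {
      dice(binarize(prob_volumes[[i]], t,
                    grid = reference_masks[[i]]),
           reference_masks[[i]])
    }, numeric(1)))
  }, numeric(1))
  best <- which(scores >= max(scores) - 1e-12)
  best <- best[order(abs(candidates[best] - 0.5), candidates[best])]
  candidates[best[1]]
}

#' Binarize a probability volume
#'
#' Voxel is 1 iff its probability is at least `t`; masks therefore
#' shrink monotonically as `t` grows.
#'
#' @param prob probability [image_volume] or 3D array in `[0, 1]`.
#' @param t threshold, strictly inside (0, 1).
#' @param grid reference grid when `prob` is a plain array.
#' @return A [mask_volume].
#' @export
binarize <- function(prob, t, grid = NULL) {
  stop_if_not(is.numeric(t) && length(t) == 1 && t > 0 && t < 1,
              "threshold must lie strictly in (0, 1)")
  if (inherits(prob, "image_volume")) {
    mask_volume(array(as.integer(prob$voxels >= t), dim(prob$voxels)), prob)
  } else {
    stop_if_not(!is.null(grid), "grid required for a plain array")
    mask_volume(array(as.integer(prob >= t), dim(prob)), grid)
  }
}

#' Fill single gap slices by inter-slice interpolation
#'
#' An empty slice whose immediate superior and inferior neighbours are
#' both non-empty (a "gap" slice the network skipped) is filled with
#' the per-pixel mean of the two neighbour masks thresholded strictly
#' above 0.5 — i.e. the intersection of the neighbours, so disjoint
#' neighbours fill nothing. The emptiness pattern is taken from the
#' input (one pass, no cascading); boundary slices and runs of two or
#' more empty slices are untouched. The operation never removes voxels
#' and is idempotent.
#'
#' @param m a [mask_volume].
#' @return A [mask_volume].
#' @export
fill_gap_slices <- function(m) {
  stop_if_not(inherits(m, "mask_volume"), "m must be a mask_volume")
  d <- dim(m$voxels)
  if (d[3] < 3) return(m)
  empty <- !apply(m$voxels == 1L, 3, any)
  out <- m$voxels
  for (k in 2:(d[3] - 1)) {
    if (empty[k] && !empty[k - 1] && !empty[k + 1]) {
      out[, , k] <- as.integer(
        (m$voxels[, , k - 1] + m$voxels[, , k + 1]) / 2 > 0.5)
    }
  }
  m$voxels <- out
  m
}

# Keep only the largest 3D 26-connected component (optional filter).
largest_component_3d <- function(m) {
  v <- m$voxels
  d <- dim(v)
  lab <- array(0L, d)
  nxt <- 0L
  for (k in seq_len(d[3])) {
    sl <- cc_label(matrix(as.integer(v[, , k]), d[1]), 8L)
    sl[sl > 0] <- sl[sl > 0] + nxt
    lab[, , k] <- sl
    nxt <- max(nxt, if (length(sl)) max(sl) else 0L)
  }
  # merge labels across adjacent slices (union-find over overlaps)
  parent <- seq_len(nxt)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (k in seq_len(d[3] - 1)) {
    a <- lab[, , k]; b <- lab[, , k + 1]
    touch <- a > 0L & b > 0L
    if (!any(touch)) next
    pairs <- unique(cbind(a[touch], b[touch]))
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  if (nxt == 0L) return(m)
  roots <- vapply(seq_len(nxt), find, integer(1))
  flat <- lab
  flat[flat > 0L] <- roots[flat[flat > 0L]]
  sizes <- tabulate(flat[flat > 0L])
  keep <- which.max(sizes)
  m$voxels <- array(as.integer(flat == keep), d)
  m
}

#' Predict one gland structure from CT
#'
#' The full inference path of the laterality-pooled model: for the
#' right gland the CT is fed straight through the network; for the left
#' gland the CT is mirrored laterally before prediction and the
#' probability map mirrored back. The probability volume is then
#' binarized at the model's tuned threshold, single gap slices are
#' interpolated, optionally only the largest 3D component is kept, and
#' closed contours are extracted.
#'
#' @param model a trained model with its binarization `threshold` set
#'   (see [select_threshold()]); any object with a [predict_slices()]
#'   method works.
#' @param ct a CT [image_volume] in HU.
#' @param side `"right"` or `"left"`.
#' @param name structure name; defaults to `"Tubarial_R"` /
#'   `"Tubarial_L"`.
#' @param keep_largest keep only the largest 3D connected component of
#'   the binarized prediction (off by default).
#' @param threshold optional threshold overriding the model's.
#' @return An object of class `prediction_result`: a list with
#'   `probability` (volume), `threshold`, `mask` ([mask_volume]),
#'   `structure` ([structure_set]) and `laterality`.
#' @export
predict_structure <- function(model, ct, side = c("right", "left"),
                              name = NULL, keep_largest = FALSE,
                              threshold = NULL) {
  side <- match.arg(side)
  threshold <- threshold %||% model$threshold
  if (is.null(threshold) || is.na(threshold)) {
    stop("binarization threshold unset: run select_threshold() first",
         call. = FALSE)
  }
  name <- name %||% if (side == "right") "Tubarial_R" else "Tubarial_L"
  prob <- if (side == "right") {
    predict_slices(model, ct)
  } else {
    mirror_lateral(predict_slices(model, mirror_lateral(ct)))
  }
  mask <- binarize(prob, threshold)
  if (keep_largest) mask <- largest_component_3d(mask)
  mask <- fill_gap_slices(mask)
  ss <- extract_contours(mask, name = name, laterality = side)
  structure(list(probability = prob, threshold = threshold, mask = mask,
                 structure = ss, laterality = side),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s gland, threshold %.2f, %d voxels, %d contour(s)\n",
              x$laterality, x$threshold, sum(x$mask$voxels),
              length(x$structure$structures[[1]]$contours)))
  invisible(x)
}

#' Set a model's binarization threshold
#'
#' @param model a [multiresunet] (or compatible model object).
#' @param threshold value in (0, 1).
#' @return The model with `threshold` set.
#' @export
set_threshold <- function(model, threshold) {
  stop_if_not(threshold > 0 && threshold < 1,
              "threshold must lie strictly in (0, 1)")
  model$threshold <- threshold
  model
}
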