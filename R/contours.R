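# Mask -> contour conversion. Edge pixels are found with a Canny
# detector run on the (0/1) mask slice, grouped into 8-connected
# components, ordered into closed polygons by nearest-neighbour
# marching, and localized to sub-pixel precision at the 0.5 level of the
# smoothed mask (the half-way crossing between a foreground and a
# background pixel center), so that re-rasterizing a contour reproduces
# the mask it came from.

gauss_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with zero padding (H x W matrix).
sep_convolve <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  padded <- matrix(0, H + 2 * r, W)
  padded[(r + 1):(r + H), ] <- m
  v <- matrix(0, H, W)
  for (t in seq_along(k)) v <- v + k[t] * padded[t:(t + H - 1), , drop = FALSE]
  padded <- matrix(0, H, W + 2 * r)
  padded[, (r + 1):(r + W)] <- v
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * padded[, t:(t + W - 1), drop = FALSE]
  out
}

# Shift a matrix by (dr, dc), zero-filling.
mat_shift <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

sobel_gradients <- function(I) {
  # +col (x) and +row (y) derivatives, Sobel / 8 normalization
  gx <- (mat_shift(I, 0, -1) - mat_shift(I, 0, 1)) * 2 +
    (mat_shift(I, -1, -1) - mat_shift(I, -1, 1)) +
    (mat_shift(I, 1, -1) - mat_shift(I, 1, 1))
  gy <- (mat_shift(I, -1, 0) - mat_shift(I, 1, 0)) * 2 +
    (mat_shift(I, -1, -1) - mat_shift(I, 1, -1)) +
    (mat_shift(I, -1, 1) - mat_shift(I, 1, 1))
  list(gx = gx / 8, gy = gy / 8)
}

# Canny edge pixels of a binary slice. Returns row/col indices, the
# smoothed intensity and gradient components at those pixels.
canny_slice <- function(mask, low = 0.1, high = 0.2, sigma = 1) {
  I <- sep_convolve(mask, gauss_kernel(sigma))
  g <- sobel_gradients(I)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx == 0) return(NULL)
  magn <- mag / mx
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  nb <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))  # (dr, dc) per sector
  keep <- matrix(FALSE, nrow(mask), ncol(mask))
  for (s in 0:3) {
    d <- nb[[s + 1]]
    sel <- sector == s
    keep[sel] <- sel[sel] &
      (magn >= mat_shift(magn, d[1], d[2]))[sel] &
      (magn >= mat_shift(magn, -d[1], -d[2]))[sel]
  }
  weak <- keep & magn >= low
  strong <- keep & magn >= high
  if (!any(strong)) return(NULL)
  lab <- cc_label(matrix(as.integer(weak), nrow(mask)), 8L)
  ok <- sort(unique(lab[strong]))
  edge <- weak & (lab %in% ok)
  idx <- which(edge, arr.ind = TRUE)
  list(row = idx[, 1], col = idx[, 2],
       I = I[edge], gx = g$gx[edge], gy = g$gy[edge])
}

# Greedy nearest-neighbour ordering of edge pixels into a closed loop.
order_edge_pixels <- function(row, col) {
  n <- length(row)
  if (n <= 2L) return(seq_len(n))
  order_out <- integer(n)
  used <- logical(n)
  cur <- which.min(row * 1e4 + col)
  for (t in seq_len(n)) {
    order_out[t] <- cur
    used[cur] <- TRUE
    if (t == n) break
    d2 <- (row - row[cur])^2 + (col - col[cur])^2
    d2[used] <- Inf
    cur <- which.min(d2)
  }
  order_out
}

# Axis-aligned rectangle polygon (mm) around a pixel bounding box.
pixel_outline_polygon <- function(rows, cols, ax, sp) {
  x0 <- min(ax$x[cols]) - sp[2] / 2; x1 <- max(ax$x[cols]) + sp[2] / 2
  y0 <- min(ax$y[rows]) - sp[1] / 2; y1 <- max(ax$y[rows]) + sp[1] / 2
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Extract closed contours from a binary mask volume
#'
#' Per slice, edge pixels of the 0/1 mask are detected with a Canny
#' detector (Gaussian sigma 1; hysteresis thresholds 0.1/0.2 on the
#' normalized gradient magnitude -- any setting detects a binary step
#' edge), grouped into 8-connected components (one polygon each),
#' ordered by nearest-neighbour marching and refined to the sub-pixel
#' 0.5-level crossing along the local gradient before being mapped to
#' patient millimetres through the grid geometry. Components too small
#' for an edge ring (single or few pixels) are kept as their half-voxel
#' outline rectangle rather than dropped.
#'
#' @param m a [mask_volume].
#' @param name structure name for the result (default `"structure"`).
#' @param laterality `"right"`, `"left"` or `"none"`.
#' @param low,high Canny hysteresis thresholds on the normalized
#'   gradient magnitude.
#' @return A [structure_set] with one structure (possibly empty).
#' @export
extract_contours <- function(m, name = "structure", laterality = "none",
                             low = 0.1, high = 0.2) {
  stop_if_not(inherits(m, "mask_volume"), "m must be a mask_volume")
  ax <- grid_axes(m)
  sp <- m$spacing_mm
  contours <- list()
  d <- dim(m$voxels)
  for (k in seq_len(d[3])) {
    sl <- m$voxels[, , k]
    if (!any(sl == 1L)) next
    lab <- cc_label(matrix(as.integer(sl), d[1]), 8L)
    for (cid in seq_len(max(lab))) {
      comp <- lab == cid
      sub <- matrix(0, d[1], d[2]); sub[comp] <- 1
      # components too small for an edge ring keep their pixel outline
      ed <- if (sum(comp) >= 5L) canny_slice(sub, low = low, high = high)
      poly <- NULL
      if (!is.null(ed) && length(ed$row) >= 3L) {
        ord <- order_edge_pixels(ed$row, ed$col)
        gmag <- sqrt(ed$gx^2 + ed$gy^2)
        tt <- pmin(1, pmax(-1, (ed$I - 0.5) / pmax(gmag, 1e-9)))
        # step from the pixel center toward the 0.5 crossing (downhill)
        col_sub <- ed$col - tt * ed$gx / pmax(gmag, 1e-9)
        row_sub <- ed$row - tt * ed$gy / pmax(gmag, 1e-9)
        poly <- cbind(m$origin_mm[1] + (col_sub[ord] - 1) * sp[2],
                      m$origin_mm[2] + (row_sub[ord] - 1) * sp[1])
        # drop consecutive duplicate vertices
        dup <- c(FALSE, rowSums(abs(diff(poly))) < 1e-9)
        poly <- poly[!dup, , drop = FALSE]
      }
      if (is.null(poly) || nrow(poly) < 3L) {
        idx <- which(comp, arr.ind = TRUE)
        poly <- pixel_outline_polygon(idx[, 1], idx[, 2], ax, sp)
      }
      contours[[length(contours) + 1L]] <- list(z = ax$z[k], xy = poly)
    }
  }
  out <- list(list(contours = contours, laterality = laterality))
  names(out) <- name
  structure_set(out)
}
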