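# Minimal DICOM codec: explicit-VR little-endian single-frame image
# series (CT/PT) and RTSTRUCT structure sets. Covers exactly the
# attributes this pipeline produces and consumes; files are conformant
# enough for third-party readers (pydicom reads them unchanged).

UID_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_PT <- "1.2.840.10008.5.1.4.1.1.128"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

r16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
r32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
u16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1L])
u32 <- function(b, i) as.numeric(b[i]) + 256 * as.numeric(b[i + 1L]) +
  65536 * as.numeric(b[i + 2L]) + 16777216 * as.numeric(b[i + 3L])

enc_int16 <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                                  endian = "little")
dec_int16 <- function(b) readBin(b, integer(), n = length(b) / 2L,
                                 size = 2L, signed = TRUE, endian = "little")

dcm_string <- function(value, pad = charToRaw(" ")) {
  s <- paste(value, collapse = "\\")
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, pad)
  b
}

# DS values: up to 16 bytes; %.10g keeps sub-micrometre coordinates and
# small rescale slopes exact enough for lossless-in-practice round trips.
fmt_ds <- function(x) sprintf("%.10g", x)

# One data element in explicit VR little endian.
dcm_element <- function(group, element, vr, value) {
  body <- if (is.raw(value)) value
  else if (vr %in% c("UI")) dcm_string(value, pad = as.raw(0))
  else if (vr %in% c("US")) enc_int16(value)
  else if (vr %in% c("UL")) r32(value)
  else dcm_string(value)
  len <- length(body)
  hdr <- c(r16(group), r16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) hdr <- c(hdr, as.raw(c(0, 0)), r32(len))
  else hdr <- c(hdr, r16(len))
  c(hdr, body)
}

dcm_item <- function(content) c(r16(0xFFFE), r16(0xE000), r32(length(content)),
                                content)
dcm_sequence <- function(group, element, items) {
  dcm_element(group, element, "SQ", do.call(c, c(list(raw()), items)))
}

# File meta (group 2) + preamble around a dataset body.
dcm_file <- function(sop_class, sop_instance, body) {
  meta_elems <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", "2.25.874661159113829911"))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_elems)), meta_elems)
  c(raw(128), charToRaw("DICM"), meta, body)
}

# ---- parsing ---------------------------------------------------------------

# Parse explicit-VR-LE elements in bytes[start:end] into a named list
# "GGGG,EEEE" -> list(vr, bytes) (SQ values parsed into item lists).
parse_elements <- function(b, start, end) {
  out <- list()
  i <- start
  while (i + 7L <= end) {
    g <- u16(b, i); e <- u16(b, i + 2L)
    vr <- rawToChar(b[(i + 4L):(i + 5L)])
    if (vr %in% LONG_VRS) {
      len <- u32(b, i + 8L); i <- i + 12L
    } else {
      len <- u16(b, i + 6L); i <- i + 8L
    }
    key <- sprintf("%04X,%04X", g, e)
    if (vr == "SQ") {
      if (len == 4294967295) {
        parsed <- parse_sq_items(b, i, end, undefined = TRUE)
      } else {
        parsed <- parse_sq_items(b, i, i + len - 1L, undefined = FALSE)
      }
      out[[key]] <- list(vr = vr, items = parsed$items)
      i <- parsed$next_i
    } else {
      stop_if_not(len != 4294967295, "undefined length outside SQ")
      val <- if (len > 0) b[i:(i + len - 1L)] else raw()
      out[[key]] <- list(vr = vr, bytes = val)
      i <- i + len
    }
  }
  out
}

parse_sq_items <- function(b, i, end, undefined) {
  items <- list()
  repeat {
    if (undefined) {
      stop_if_not(i + 7L <= length(b), "truncated sequence")
    } else if (i > end) break
    g <- u16(b, i); e <- u16(b, i + 2L)
    if (undefined && g == 0xFFFE && e == 0xE0DD) { i <- i + 8L; break }
    stop_if_not(g == 0xFFFE && e == 0xE000, "malformed sequence item")
    len <- u32(b, i + 4L)
    i <- i + 8L
    if (len == 4294967295) {
      # undefined-length item: scan to item delimiter
      j <- i
      repeat {
        stop_if_not(j + 7L <= length(b), "truncated item")
        if (u16(b, j) == 0xFFFE && u16(b, j + 2L) == 0xE00D) break
        jr <- rawToChar(b[(j + 4L):(j + 5L)])
        j <- j + (if (jr %in% LONG_VRS) 12L + u32(b, j + 8L) else 8L + u16(b, j + 6L))
      }
      items[[length(items) + 1L]] <- parse_elements(b, i, j - 1L)
      i <- j + 8L
    } else {
      items[[length(items) + 1L]] <-
        if (len > 0) parse_elements(b, i, i + len - 1L) else list()
      i <- i + len
    }
  }
  list(items = items, next_i = i)
}

read_dicom_file <- function(path) {
  b <- readBin(path, raw(), n = file.size(path))
  stop_if_not(length(b) > 132 && rawToChar(b[129:132]) == "DICM",
              "%s is not a DICOM file", path)
  i <- 133L
  # file meta group (always explicit LE)
  stop_if_not(u16(b, i) == 2L, "missing file meta group")
  meta_len <- u32(b, i + 8L)
  meta <- parse_elements(b, i, i + 11L + meta_len)
  ts <- dcm_str(meta, "0002,0010")
  stop_if_not(identical(ts, UID_EXPLICIT_LE),
              "unsupported transfer syntax '%s'", ts)
  parse_elements(b, i + 12L + meta_len, length(b))
}

dcm_str <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v$bytes[v$bytes != as.raw(0)]))
}
dcm_num <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  if (v$vr %in% c("US", "SS")) {
    return(dec_int16(v$bytes))
  }
  if (v$vr == "UL") {
    return(vapply(seq(1L, length(v$bytes), by = 4L),
                  function(i) u32(v$bytes, i), numeric(1)))
  }
  s <- dcm_str(el, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

# ---- image series ----------------------------------------------------------

#' Write an image volume as a single-frame DICOM series
#'
#' Emits one explicit-VR little-endian file per axial slice. Volumes
#' whose values are all integers representable in 16 bits (e.g. CT in
#' HU) are stored losslessly with rescale slope 1; other volumes (e.g.
#' PET activity) are quantized to 16 bits with a per-series rescale
#' slope/intercept.
#'
#' @param v an [image_volume].
#' @param path directory to create/write into.
#' @param patient_id Patient ID tag value.
#' @param frame_of_reference_uid optional frame-of-reference UID (one is
#'   generated if omitted).
#' @return Invisibly, the written file paths (with the series and
#'   frame-of-reference UIDs as attributes).
#' @export
write_image_series <- function(v, path, patient_id = "PHANTOM",
                               frame_of_reference_uid = NULL) {
  stop_if_not(inherits(v, "image_volume"), "v must be an image_volume")
  d <- dim(v$voxels)
  stop_if_not(prod(d) > 0, "cannot write an empty volume")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  stop_if_not(dir.exists(path), "cannot create directory %s", path)
  vox <- v$voxels
  if (all(vox == round(vox)) && max(abs(vox)) <= 32767) {
    slope <- 1; intercept <- 0
  } else {
    rng <- range(vox)
    slope <- max((rng[2] - rng[1]) / 64000, 1e-12)
    intercept <- (rng[1] + rng[2]) / 2
  }
  series_uid <- uid_generate()
  study_uid <- uid_generate()
  for_uid <- frame_of_reference_uid %||% uid_generate()
  sop_class <- if (v$modality == "CT") UID_CT else UID_PT
  modality <- if (v$modality == "CT") "CT" else "PT"
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    stored <- round((v$voxels[, , k] - intercept) / slope)
    sop_uid <- uid_generate()
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", sop_class),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", modality),
      dcm_element(0x0010, 0x0010, "PN", patient_id),
      dcm_element(0x0010, 0x0020, "LO", patient_id),
      dcm_element(0x0018, 0x0050, "DS", fmt_ds(v$spacing_mm[3])),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0011, "IS", "1"),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS",
                  fmt_ds(c(v$origin_mm[1], v$origin_mm[2],
                           v$slice_positions_mm[k]))),
      dcm_element(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0020, 0x0052, "UI", for_uid),
      dcm_element(0x0020, 0x1041, "DS", fmt_ds(v$slice_positions_mm[k])),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[1]),
      dcm_element(0x0028, 0x0011, "US", d[2]),
      dcm_element(0x0028, 0x0030, "DS",
                  fmt_ds(c(v$spacing_mm[1], v$spacing_mm[2]))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", fmt_ds(intercept)),
      dcm_element(0x0028, 0x1053, "DS", fmt_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", enc_int16(t(stored))))
    files[k] <- file.path(path, sprintf("%s_%03d.dcm", modality, k))
    writeBin(dcm_file(sop_class, sop_uid, body), files[k])
  }
  invisible(structure(files, series_uid = series_uid,
                      frame_of_reference_uid = for_uid))
}

#' Read a single-frame DICOM image series
#'
#' Reads every `.dcm` file in a directory, requires a single series
#' (mixed series UIDs are rejected), sorts slices by axial position and
#' applies the rescale slope/intercept, yielding CT values in HU or PET
#' values in stored activity units.
#'
#' @param path directory containing one DICOM series.
#' @return An [image_volume] with attribute `frame_of_reference_uid`.
#' @export
read_image_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  stop_if_not(length(files) > 0, "no DICOM files found in %s", path)
  parsed <- lapply(files, read_dicom_file)
  series <- vapply(parsed, function(el) dcm_str(el, "0020,000E"), character(1))
  stop_if_not(length(unique(series)) == 1L,
              "directory %s mixes %d series", path, length(unique(series)))
  ipp <- lapply(parsed, function(el) dcm_num(el, "0020,0032"))
  stop_if_not(all(lengths(ipp) == 3L), "missing ImagePositionPatient")
  ord <- order(vapply(ipp, `[`, numeric(1), 3))
  parsed <- parsed[ord]; ipp <- ipp[ord]
  first <- parsed[[1]]
  rows <- dcm_num(first, "0028,0010") %||% stop("missing Rows")
  cols <- dcm_num(first, "0028,0011")
  pxs <- dcm_num(first, "0028,0030")
  for (el in parsed) {
    stop_if_not(identical(dcm_num(el, "0028,0010"), rows) &&
                  identical(dcm_num(el, "0028,0011"), cols),
                "inconsistent matrix size across slices")
    stop_if_not(max(abs(dcm_num(el, "0028,0030") - pxs)) < 1e-6,
                "non-uniform in-plane spacing across slices")
  }
  zs <- vapply(ipp, `[`, numeric(1), 3)
  dz <- if (length(zs) > 1) min(diff(zs)) else
    (dcm_num(first, "0018,0050") %||% 1)
  stop_if_not(length(zs) == 1 || all(diff(zs) > 0), "duplicate slice positions")
  vox <- array(0, c(rows, cols, length(parsed)))
  for (k in seq_along(parsed)) {
    el <- parsed[[k]]
    slope <- dcm_num(el, "0028,1053") %||% 1
    intercept <- dcm_num(el, "0028,1052") %||% 0
    stored <- dec_int16(el[["7FE0,0010"]]$bytes)
    vox[, , k] <- t(matrix(stored, nrow = cols, ncol = rows)) * slope + intercept
  }
  modality <- if (identical(dcm_str(first, "0008,0060"), "PT")) "PET" else "CT"
  out <- image_volume(vox,
                      origin_mm = c(ipp[[1]][1], ipp[[1]][2], zs[1]),
                      spacing_mm = c(pxs[1], pxs[2], dz),
                      modality = modality,
                      slice_positions_mm = zs)
  attr(out, "frame_of_reference_uid") <- dcm_str(first, "0020,0052")
  out
}

# ---- RTSTRUCT --------------------------------------------------------------

#' Write a structure set as a DICOM RTSTRUCT file
#'
#' Contours are stored as `CLOSED_PLANAR` contour items with vertices in
#' patient mm; structure laterality is recorded in the RT ROI
#' observation label. Write-then-read preserves names exactly and
#' vertices to better than 1e-3 mm.
#'
#' @param s a [structure_set].
#' @param reference an [image_volume] (used for its frame-of-reference
#'   UID attribute, when present).
#' @param path output file path.
#' @param frame_of_reference_uid optional explicit frame-of-reference
#'   UID; defaults to the reference's, else a generated one.
#' @return Invisibly, `path`.
#' @export
write_rtstruct <- function(s, reference = NULL, path,
                           frame_of_reference_uid = NULL) {
  stop_if_not(inherits(s, "structure_set"), "s must be a structure_set")
  for_uid <- frame_of_reference_uid %||%
    attr(reference, "frame_of_reference_uid") %||% uid_generate()
  nms <- structure_names(s)
  roi_items <- list(); contour_items <- list(); obs_items <- list()
  for (r in seq_along(nms)) {
    st <- s$structures[[nms[r]]]
    roi_items[[r]] <- dcm_item(c(
      dcm_element(0x3006, 0x0022, "IS", as.character(r)),
      dcm_element(0x3006, 0x0024, "UI", for_uid),
      dcm_element(0x3006, 0x0026, "LO", nms[r]),
      dcm_element(0x3006, 0x0036, "CS", "AUTOMATIC")))
    cts <- lapply(st$contours, function(ct) {
      pts <- cbind(ct$xy, ct$z)
      dcm_item(c(
        dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", as.character(nrow(pts))),
        dcm_element(0x3006, 0x0050, "DS", fmt_ds(as.numeric(t(pts))))))
    })
    contour_items[[r]] <- dcm_item(c(
      dcm_element(0x3006, 0x002A, "IS", "255\\0\\0"),
      dcm_sequence(0x3006, 0x0040, cts),
      dcm_element(0x3006, 0x0084, "IS", as.character(r))))
    obs_items[[r]] <- dcm_item(c(
      dcm_element(0x3006, 0x0082, "IS", as.character(r)),
      dcm_element(0x3006, 0x0084, "IS", as.character(r)),
      dcm_element(0x3006, 0x0085, "SH", st$laterality),
      dcm_element(0x3006, 0x00A4, "CS", "ORGAN")))
  }
  sop_uid <- uid_generate()
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x0010, 0x0010, "PN", "PHANTOM"),
    dcm_element(0x0010, 0x0020, "LO", "PHANTOM"),
    dcm_element(0x0020, 0x0052, "UI", for_uid),
    dcm_element(0x3006, 0x0002, "SH", "tubseg"),
    dcm_sequence(0x3006, 0x0020, roi_items),
    dcm_sequence(0x3006, 0x0039, contour_items),
    dcm_sequence(0x3006, 0x0080, obs_items))
  writeBin(dcm_file(UID_RTSTRUCT, sop_uid, body), path)
  invisible(path)
}

#' Read a DICOM RTSTRUCT file
#'
#' @param path RTSTRUCT file path.
#' @param reference optional [image_volume] whose frame-of-reference UID
#'   (attribute set by [read_image_series()]) is checked against the
#'   structure set's.
#' @param on_frame_mismatch `"warn"` (default) or `"error"` when the
#'   frame-of-reference UIDs disagree.
#' @return A [structure_set].
#' @export
read_rtstruct <- function(path, reference = NULL,
                          on_frame_mismatch = c("warn", "error")) {
  on_frame_mismatch <- match.arg(on_frame_mismatch)
  el <- read_dicom_file(path)
  ref_uid <- attr(reference, "frame_of_reference_uid")
  this_uid <- dcm_str(el, "0020,0052")
  if (!is.null(ref_uid) && !is.null(this_uid) && !identical(ref_uid, this_uid)) {
    msg <- sprintf("RTSTRUCT frame of reference %s does not match reference %s",
                   this_uid, ref_uid)
    if (on_frame_mismatch == "error") stop(msg, call. = FALSE) else warning(msg)
  }
  rois <- el[["3006,0020"]]$items
  stop_if_not(!is.null(rois), "missing StructureSetROISequence")
  names_by_number <- list(); order_numbers <- numeric(0)
  for (it in rois) {
    num <- dcm_num(it, "3006,0022")
    names_by_number[[as.character(num)]] <- dcm_str(it, "3006,0026")
    order_numbers <- c(order_numbers, num)
  }
  lat_by_number <- list()
  for (it in el[["3006,0080"]]$items %||% list()) {
    lab <- dcm_str(it, "3006,0085") %||% "none"
    if (!lab %in% c("right", "left")) lab <- "none"
    lat_by_number[[as.character(dcm_num(it, "3006,0084"))]] <- lab
  }
  contours_by_number <- list()
  for (it in el[["3006,0039"]]$items %||% list()) {
    num <- as.character(dcm_num(it, "3006,0084"))
    cts <- lapply(it[["3006,0040"]]$items %||% list(), function(ci) {
      pts <- matrix(dcm_num(ci, "3006,0050"), ncol = 3, byrow = TRUE)
      list(z = pts[1, 3], xy = pts[, 1:2, drop = FALSE])
    })
    contours_by_number[[num]] <- cts
  }
  structures <- list()
  for (num in order_numbers) {
    key <- as.character(num)
    structures[[names_by_number[[key]]]] <-
      list(contours = contours_by_number[[key]] %||% list(),
           laterality = lat_by_number[[key]] %||% "none")
  }
  structure_set(structures)
}
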