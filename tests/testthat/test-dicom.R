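test_that("CT series round trip is lossless; PET keeps modality", {
  ph <- generate_phantom(small_spec(noise_sd = 0.1, seed = 4L))
  td <- withr::local_tempdir()
  write_image_series(ph$ct, file.path(td, "ct"))
  v <- read_image_series(file.path(td, "ct"))
  expect_identical(v$voxels, ph$ct$voxels)        # integer HU, bit-exact
  expect_lt(max(abs(v$origin_mm - ph$ct$origin_mm)), 1e-6)
  expect_lt(max(abs(v$spacing_mm - ph$ct$spacing_mm)), 1e-6)
  expect_lt(max(abs(v$slice_positions_mm - ph$ct$slice_positions_mm)), 1e-6)
  expect_identical(v$modality, "CT")

  write_image_series(ph$pet, file.path(td, "pet"))
  vp <- read_image_series(file.path(td, "pet"))
  expect_identical(vp$modality, "PET")
  expect_lt(max(abs(vp$voxels - ph$pet$voxels)), 1e-3)
  expect_equal(length(list.files(file.path(td, "pet"))),
               dim(ph$pet$voxels)[3])
})

test_that("mixed series and empty volumes are rejected", {
  ph <- generate_phantom(tiny_spec(seed = 2L))
  td <- withr::local_tempdir()
  mix <- file.path(td, "mix")
  write_image_series(ph$ct, mix)
  write_image_series(ph$pet, mix)  # second series into the same directory
  expect_error(read_image_series(mix), "mixes")

  empty <- image_volume(array(numeric(0), c(0, 0, 0)), c(0, 0, 0),
                        c(1, 1, 1), "CT")
  expect_error(write_image_series(empty, file.path(td, "e")), "empty")
})

test_that("RTSTRUCT round trip preserves names, vertices and laterality", {
  ph <- generate_phantom(small_spec(noise_sd = 0))
  td <- withr::local_tempdir()
  rt <- file.path(td, "rs.dcm")
  write_rtstruct(ph$truth, NULL, rt)
  s2 <- read_rtstruct(rt)
  expect_identical(structure_names(s2), structure_names(ph$truth))
  expect_identical(s2$structures$Tubarial_R$laterality, "right")
  expect_identical(s2$structures$Tubarial_L$laterality, "left")
  for (i in seq_along(ph$truth$structures$Tubarial_R$contours)) {
    a <- ph$truth$structures$Tubarial_R$contours[[i]]
    b <- s2$structures$Tubarial_R$contours[[i]]
    expect_lt(max(abs(a$xy - b$xy)), 1e-3)
    expect_lt(abs(a$z - b$z), 1e-3)
  }
  # rasterization of original and round-tripped structures is identical
  expect_identical(rasterize(s2, ph$ct, "Tubarial_R")$voxels,
                   rasterize(ph$truth, ph$ct, "Tubarial_R")$voxels)

  # empty structure preserved as empty
  es <- structure_set(list(empty_roi = list(contours = list()),
                           square = list(contours = list(list(
                             z = 0, xy = cbind(c(0, 20, 20, 0),
                                               c(0, 0, 20, 20)))))))
  rt2 <- file.path(td, "rs2.dcm")
  write_rtstruct(es, NULL, rt2)
  s3 <- read_rtstruct(rt2)
  expect_identical(structure_names(s3), c("empty_roi", "square"))
  expect_length(s3$structures$empty_roi$contours, 0)
  expect_lt(max(abs(s3$structures$square$contours[[1]]$xy -
                      es$structures$square$contours[[1]]$xy)), 1e-3)
})

test_that("frame-of-reference mismatches warn or reject as configured", {
  ph <- generate_phantom(tiny_spec(seed = 5L))
  td <- withr::local_tempdir()
  write_image_series(ph$ct, file.path(td, "ct"))
  v <- read_image_series(file.path(td, "ct"))
  rt <- file.path(td, "rs.dcm")
  write_rtstruct(ph$truth, NULL, rt,
                 frame_of_reference_uid = "2.25.111")
  expect_warning(read_rtstruct(rt, v), "frame of reference")
  expect_error(read_rtstruct(rt, v, on_frame_mismatch = "error"),
               "frame of reference")
  # matching frame: silent
  rt2 <- file.path(td, "rs2.dcm")
  write_rtstruct(ph$truth, v, rt2)
  expect_silent(read_rtstruct(rt2, v))
})

test_that("written DICOM files are readable by an independent implementation", {
  ph <- generate_phantom(tiny_spec(seed = 6L))
  td <- withr::local_tempdir()
  write_image_series(ph$ct, file.path(td, "ct"))
  write_rtstruct(ph$truth, NULL, file.path(td, "rs.dcm"))
  script <- file.path(td, "check.py")
  writeLines(c(
    "import sys, glob, json, pydicom",
    "d = sys.argv[1]",
    "files = sorted(glob.glob(d + '/ct/*.dcm'))",
    "ds = pydicom.dcmread(files[0])",
    "hu = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)",
    "rs = pydicom.dcmread(d + '/rs.dcm')",
    "out = {",
    "  'modality': ds.Modality,",
    "  'rows': int(ds.Rows), 'cols': int(ds.Columns),",
    "  'ipp': [float(x) for x in ds.ImagePositionPatient],",
    "  'hu00': float(hu[0, 0]),",
    "  'rois': [r.ROIName for r in rs.StructureSetROISequence],",
    "  'npts': int(rs.ROIContourSequence[0].ContourSequence[0].NumberOfContourPoints)",
    "}",
    "print(json.dumps(out))"), script)
  out <- system2("python", c(script, td), stdout = TRUE)
  info <- strsplit(gsub('[\\{\\}"\\[\\]]', "", out), ",\\s*")[[1]]
  expect_match(out, '"modality": "CT"')
  expect_match(out, sprintf('"rows": %d', dim(ph$ct$voxels)[1]))
  expect_match(out, '"rois": \\["Tubarial_R", "Tubarial_L"\\]')
  expect_match(out, sprintf('"hu00": %s',
                            format(ph$ct$voxels[1, 1, 1], nsmall = 1)))
})
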