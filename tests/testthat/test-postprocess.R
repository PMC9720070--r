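prob_volume <- function(values, dim3 = c(8, 8, 3)) {
  image_volume(array(values, dim3), c(0, 0, 0), c(1, 1, 3), "CT")
}

test_that("threshold selection maximizes validation Dice, ties toward 0.5", {
  grid <- prob_volume(0)
  ref <- mask_volume(array(as.integer(stats::runif(192) < 0.3), c(8, 8, 3)),
                     grid)
  # probabilities identical to the reference: every candidate is perfect
  exact <- prob_volume(as.numeric(ref$voxels))
  expect_equal(select_threshold(list(exact), list(ref)), 0.5)

  # two-valued probabilities 0.2 / 0.8: all candidates in (0.2, 0.8]
  # are optimal; the grid value nearest 0.5 is returned
  pv <- prob_volume(0.2 + 0.6 * ref$voxels)
  expect_equal(select_threshold(list(pv), list(ref)), 0.5)
  # verify optimality by exhaustive enumeration
  cands <- seq(0.05, 0.95, by = 0.05)
  scores <- vapply(cands, function(t) dice(binarize(pv, t), ref), numeric(1))
  expect_equal(max(scores), dice(binarize(pv, 0.5), ref))

  # empty reference, low uniform probability: thresholds above 0.1 give
  # the perfect empty/empty agreement
  empty_ref <- mask_volume(array(0L, c(8, 8, 3)), grid)
  low <- prob_volume(0.1)
  expect_equal(select_threshold(list(low), list(empty_ref)), 0.5)

  expect_error(select_threshold(list(), list()), "empty")
})

test_that("binarization is monotone with the documented boundary rule", {
  pv <- prob_volume(c(0.4, 0.6), c(1, 2, 1))
  expect_identical(as.integer(binarize(pv, 0.5)$voxels), c(0L, 1L))
  expect_identical(as.integer(binarize(pv, 0.6)$voxels), c(0L, 1L))  # >= t
  pos <- prob_volume(stats::runif(192, 0.01, 1))
  expect_true(all(binarize(pos, 0.001)$voxels == 1))
  m1 <- binarize(pos, 0.3); m2 <- binarize(pos, 0.6)
  expect_true(all(m2$voxels <= m1$voxels))
  expect_error(binarize(pos, 0), "strictly")
  expect_error(binarize(pos, 1), "strictly")
})

test_that("gap filling interpolates single gaps only, idempotently", {
  base <- disc_mask(5, n = 16L, slices = 7L)
  v <- base$voxels
  v[, , 4] <- 0L                       # single interior gap
  gap <- mask_volume(v, base)
  filled <- fill_gap_slices(gap)
  expect_identical(filled$voxels[, , 4], base$voxels[, , 4])

  # identical neighbours reproduce the neighbour mask exactly
  expect_identical(fill_gap_slices(filled)$voxels, filled$voxels)
  expect_true(all(filled$voxels >= gap$voxels))    # never removes voxels

  # disjoint neighbours: strict majority rule fills nothing
  v2 <- array(0L, c(16, 16, 3))
  v2[2:5, 2:5, 1] <- 1L
  v2[10:14, 10:14, 3] <- 1L
  disjoint <- mask_volume(v2, base_grid(16, 3))
  expect_equal(sum(fill_gap_slices(disjoint)$voxels[, , 2]), 0)

  # double gaps and boundary gaps stay untouched
  v3 <- base$voxels
  v3[, , 3] <- 0L; v3[, , 4] <- 0L; v3[, , 1] <- 0L
  double <- mask_volume(v3, base)
  expect_identical(fill_gap_slices(double)$voxels, v3)

  # overlapping but different neighbours: intersection is filled
  v4 <- array(0L, c(16, 16, 3))
  v4[2:8, 2:8, 1] <- 1L
  v4[5:12, 5:12, 3] <- 1L
  part <- fill_gap_slices(mask_volume(v4, base_grid(16, 3)))
  expect_identical(part$voxels[, , 2], v4[, , 1] * v4[, , 3])
})

test_that("left prediction is the mirrored right pipeline, exactly", {
  # stub model: pointwise (mirror-equivariant) probability map
  stub <- structure(list(threshold = 0.5, window_hu = c(-100, 300)),
                    class = "pointwise_stub")
  registerS3method("predict_slices", "pointwise_stub",
                   function(model, ct) {
                     out <- ct
                     out$voxels <- pmin(pmax((ct$voxels - 40) / 100, 0), 1)
                     out
                   }, envir = asNamespace("tubseg"))
  ph <- generate_phantom(tiny_spec(noise_sd = 0.1, seed = 8L))
  right_on_mirrored <- predict_structure(stub, mirror_lateral(ph$ct),
                                         side = "right")
  left <- predict_structure(stub, ph$ct, side = "left")
  expect_identical(left$mask$voxels,
                   mirror_lateral(right_on_mirrored$mask)$voxels)
  expect_identical(left$laterality, "left")
  expect_identical(structure_names(left$structure), "Tubarial_L")

  # threshold unset -> instructive error
  stub$threshold <- NA_real_
  expect_error(predict_structure(stub, ph$ct, side = "right"),
               "select_threshold")
})

test_that("prediction on background-only input yields a valid empty result", {
  stub <- structure(list(threshold = 0.5), class = "zero_stub")
  registerS3method("predict_slices", "zero_stub",
                   function(model, ct) { ct$voxels[] <- 0.01; ct },
                   envir = asNamespace("tubseg"))
  ct <- image_volume(array(40, c(16, 16, 4)), c(0, 0, 0), c(1, 1, 3), "CT")
  pr <- predict_structure(stub, ct, side = "right")
  expect_equal(sum(pr$mask$voxels), 0)
  expect_length(pr$structure$structures$Tubarial_R$contours, 0)
  td <- withr::local_tempdir()
  rt <- file.path(td, "empty.dcm")
  write_rtstruct(pr$structure, NULL, rt)
  expect_length(read_rtstruct(rt)$structures$Tubarial_R$contours, 0)
})
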