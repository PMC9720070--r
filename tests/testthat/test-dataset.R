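test_that("CT normalization maps the window linearly onto [0, 1]", {
  v <- image_volume(array(c(-200, -100, 100, 300, 500, 0), c(1, 1, 6)),
                    c(0, 0, 0), c(1, 1, 1), "CT")
  n <- normalize_ct(v, c(-100, 300))
  expect_equal(as.numeric(n$voxels), c(0, 0, 0.5, 1, 1, 0.25))

  below <- normalize_ct(image_volume(array(-500, c(2, 2, 1)), c(0, 0, 0),
                                     c(1, 1, 1), "CT"), c(-100, 300))
  expect_true(all(below$voxels == 0))

  expect_equal(normalize_ct(n, c(0, 1))$voxels, n$voxels)  # idempotent
  expect_error(normalize_ct(v, c(300, -100)), "low < high")
})

test_that("pooling yields two samples per slice with exact mirror pairing", {
  specs <- lapply(1:3, function(i) tiny_spec(noise_sd = 0, seed = i))
  cohort <- lapply(specs, generate_phantom)
  samples <- build_pooled_dataset(cohort)
  expect_length(samples, 2 * 3 * 12)

  sides <- vapply(samples, `[[`, character(1), "pooled_side")
  expect_equal(sum(sides == "native-right"), 3 * 12)

  # noiseless symmetric phantom: mirrored-left duplicates native-right
  for (i in seq(1, length(samples), by = 2)) {
    expect_identical(samples[[i]]$image, samples[[i + 1]]$image)
    expect_identical(samples[[i]]$mask, samples[[i + 1]]$mask)
  }

  # pooled positive voxels = right-mask + left-mask voxels
  pos <- sum(vapply(samples, function(s) sum(s$mask), numeric(1)))
  truth_pos <- sum(vapply(cohort, function(p) {
    sum(rasterize(p$truth, p$ct, "Tubarial_R")$voxels) +
      sum(rasterize(p$truth, p$ct, "Tubarial_L")$voxels)
  }, numeric(1)))
  expect_equal(pos, truth_pos)

  # pooling never mixes patients
  pids <- vapply(samples, `[[`, character(1), "patient_id")
  expect_equal(sort(unique(pids)), c("P001", "P002", "P003"))
})

test_that("a missing side contributes empty masks with a warning", {
  ph <- generate_phantom(tiny_spec(noise_sd = 0))
  ph$truth <- structure_set(list(
    Tubarial_R = ph$truth$structures$Tubarial_R))
  expect_warning(samples <- build_pooled_dataset(list(ph)), "no left")
  left <- Filter(function(s) s$pooled_side == "mirrored-left", samples)
  expect_equal(sum(vapply(left, function(s) sum(s$mask), numeric(1))), 0)
  expect_length(samples, 2 * 12)
})

test_that("band_slices keeps the occupied band plus margin", {
  ph <- generate_phantom(tiny_spec(noise_sd = 0))
  samples <- build_pooled_dataset(list(ph), slice_range = band_slices(1L))
  ks <- sort(unique(vapply(samples, `[[`, integer(1), "slice_index")))
  mr <- rasterize(ph$truth, ph$ct, "Tubarial_R")
  occ <- which(apply(mr$voxels == 1, 3, any))
  expect_equal(ks, seq(max(1, min(occ) - 1), min(12, max(occ) + 1)))
})

test_that("augmentation is seeded, mask-safe and identity at zero magnitude", {
  m <- disc_mask(6, n = 32L)
  img <- 0.3 + 0.4 * m$voxels[, , 1]
  s <- training_sample(img, m$voxels[, , 1], "P1", 1)

  expect_identical(augment(s, 1, elastic_alpha = 0, perspective_scale = 0), s)

  a1 <- augment(s, 42); a2 <- augment(s, 42); a3 <- augment(s, 43)
  expect_identical(a1$image, a2$image)
  expect_false(identical(a1$image, a3$image))
  expect_true(all(a1$mask %in% c(0L, 1L)))
  expect_identical(dim(a1$image), dim(s$image))

  # mask area drift stays below 30% under default magnitudes
  area0 <- sum(s$mask)
  drift <- vapply(1:100, function(seed) {
    abs(sum(augment(s, seed)$mask) - area0) / area0
  }, numeric(1))
  expect_lt(max(drift), 0.3)

  # image/mask alignment: image is a function of the mask, so the warped
  # image re-thresholded must agree with the warped mask
  agree <- vapply(1:25, function(seed) {
    a <- augment(s, seed)
    from_img <- (a$image >= 0.5) + 0L
    2 * sum(from_img & a$mask) / (sum(from_img) + sum(a$mask))
  }, numeric(1))
  expect_gte(min(agree), 0.95)
})
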