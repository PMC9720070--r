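test_that("mirror_lateral is an exact involution mapping column i to W-i+1", {
  v <- image_volume(array(stats::rnorm(4 * 6 * 2), c(4, 6, 2)),
                    c(0, 0, 0), c(1, 1, 3), "CT")
  m <- mirror_lateral(v)
  expect_identical(mirror_lateral(m)$voxels, v$voxels)
  for (j in 1:6) expect_identical(m$voxels[, j, ], v$voxels[, 6 - j + 1, ])
  expect_identical(m$origin_mm, v$origin_mm)

  msk <- random_mask(c(8, 8, 3), p = 0.4)
  expect_identical(sum(mirror_lateral(msk)$voxels), sum(msk$voxels))
})

test_that("rasterization follows the voxel-center even-odd rule", {
  grid <- image_volume(array(0, c(20, 20, 1)),
                       c(0.5, 0.5, 0), c(1, 1, 3), "CT")
  # 10 x 10 mm square positioned so exactly 100 centers fall inside
  sq <- structure_set(list(roi = list(contours = list(
    list(z = 0, xy = cbind(c(5, 15, 15, 5), c(5, 5, 15, 15)))))))
  expect_equal(sum(rasterize(sq, grid, "roi")$voxels), 100)

  # polygon smaller than a voxel containing no center -> empty mask
  tiny <- structure_set(list(roi = list(contours = list(
    list(z = 0, xy = cbind(c(5.1, 5.4, 5.4, 5.1), c(5.1, 5.1, 5.4, 5.4)))))))
  expect_equal(sum(rasterize(tiny, grid, "roi")$voxels), 0)

  # slices without contours stay all-zero
  grid2 <- image_volume(array(0, c(20, 20, 3)), c(0.5, 0.5, 0),
                        c(1, 1, 3), "CT")
  m2 <- rasterize(sq, grid2, "roi")
  expect_equal(sum(m2$voxels[, , 2:3]), 0)
})

test_that("rasterized circle area is close to the analytic area", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  m <- rasterize(ph$truth, ph$ct, "Tubarial_R")
  # gland-body slice: area within one voxel-row of pi r^2
  body <- sum(m$voxels[, , 30])
  expect_lt(abs(body - pi * 8.5^2), 2 * 8.5 + 1)
})

test_that("contour extraction inverts rasterization on convex shapes", {
  for (r in c(3, 5, 8)) {
    m <- disc_mask(r, n = 24L)
    ss <- extract_contours(m, name = "disc")
    back <- rasterize(ss, m, "disc")
    expect_gte(dice(back, m), 0.98)
    # idempotence of rasterize . extract_contours . rasterize
    again <- rasterize(extract_contours(back, name = "disc"), m, "disc")
    expect_identical(again$voxels, back$voxels)
  }
})

test_that("contour extraction handles degenerate masks", {
  grid <- image_volume(array(0, c(16, 16, 1)), c(0, 0, 0), c(1, 1, 3), "CT")
  empty <- mask_volume(array(0L, c(16, 16, 1)), grid)
  expect_length(extract_contours(empty, name = "x")$structures$x$contours, 0)

  # two disjoint blobs on one slice -> two polygons
  v <- array(0L, c(16, 16, 1))
  v[3:6, 3:6, 1] <- 1L
  v[10:13, 10:13, 1] <- 1L
  two <- extract_contours(mask_volume(v, grid), name = "x")
  expect_length(two$structures$x$contours, 2)

  # single isolated pixel kept as a voxel-outline square
  v1 <- array(0L, c(16, 16, 1)); v1[8, 8, 1] <- 1L
  one <- extract_contours(mask_volume(v1, grid), name = "x")
  expect_length(one$structures$x$contours, 1)
  back <- rasterize(one, grid, "x")
  expect_identical(back$voxels, v1)
})

test_that("containers validate their invariants", {
  expect_error(image_volume(array(0, c(2, 2, 2)), c(0, 0, 0),
                            c(1, -1, 3), "CT"), "positive")
  expect_error(image_volume(array(0, c(2, 2, 2)), c(0, 0, 0), c(1, 1, 1),
                            "CT", slice_positions_mm = c(0, 0)), "monotonic")
  grid <- image_volume(array(0, c(4, 4, 2)), c(0, 0, 0), c(1, 1, 1), "CT")
  expect_error(mask_volume(array(2L, c(4, 4, 2)), grid), "binary")
  expect_error(mask_volume(array(0L, c(4, 4, 1)), grid), "shape")
  expect_error(structure_set(list(a = list(contours = list(
    list(z = 0, xy = cbind(1, 1)))))), "n >= 3")
})
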