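mask_from <- function(idx, dim3 = c(4, 4, 1)) {
  v <- array(0L, dim3); v[idx] <- 1L
  mask_volume(v, base_grid(dim3[1], dim3[3]))
}

test_that("Dice and Jaccard follow their set formulas and conventions", {
  a <- mask_from(1:4); b <- mask_from(3:6)
  expect_equal(dice(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  expect_equal(dice(a, mask_from(9:12)), 0)
  expect_equal(jaccard(a, mask_from(9:12)), 0)
  # |a| = 4, |b| = 4, overlap 2: DSC = 0.5, JSC = 1/3
  expect_equal(dice(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  # empty/empty convention
  e <- mask_from(integer(0))
  expect_equal(dice(e, e), 1)
  expect_equal(jaccard(e, e), 1)
  expect_equal(dice(e, a), 0)
  expect_error(dice(a, mask_from(1, c(5, 5, 1))), "grid")
})

test_that("DSC = 2J/(1+J) holds on random masks", {
  set.seed(21)
  for (i in 1:100) {
    a <- random_mask(c(8, 8, 4), p = stats::runif(1, 0.05, 0.6))
    b <- random_mask(c(8, 8, 4), p = stats::runif(1, 0.05, 0.6))
    j <- jaccard(a, b)
    expect_equal(dice(a, b), 2 * j / (1 + j), tolerance = 1e-12)
    expect_lte(j, dice(a, b))
  }
})

test_that("HD95 behaves like a robust symmetric surface distance", {
  pts <- expand.grid(x = seq(0, 20, by = 1), y = seq(0, 20, by = 1))
  plane <- structure_set(list(a = list(contours = list(
    list(z = 0, xy = as.matrix(pts))))))
  # rigid 3 mm translation orthogonal to the plane: every
  # nearest-neighbour distance is exactly 3
  shifted <- structure_set(list(a = list(contours = list(
    list(z = 3, xy = as.matrix(pts))))))
  expect_equal(hd95(plane, plane), 0)
  expect_equal(hd95(plane, shifted), 3)
  expect_equal(hd95(shifted, plane), hd95(plane, shifted))  # symmetric

  # a single 100 mm outlier among 101 points falls beyond the 95th pct
  tight <- matrix(rep(c(0, 0), 100), ncol = 2, byrow = TRUE) +
    cbind(stats::runif(100, 0, 0.1), stats::runif(100, 0, 0.1))
  with_outlier <- structure_set(list(a = list(contours = list(
    list(z = 0, xy = rbind(tight, c(100, 0)))))))
  base <- structure_set(list(a = list(contours = list(
    list(z = 0, xy = tight)))))
  expect_lt(hd95(with_outlier, base), 10)

  # translation invariance and linear scaling with spacing
  set.seed(5)
  a <- random_mask(c(10, 10, 4), 0.3)
  b <- random_mask(c(10, 10, 4), 0.3)
  g2 <- image_volume(array(0, c(10, 10, 4)), c(50, -20, 7), c(1, 1, 1), "CT")
  a2 <- mask_volume(a$voxels, g2); b2 <- mask_volume(b$voxels, g2)
  expect_equal(hd95(a2, b2), hd95(a, b), tolerance = 1e-9)
  g3 <- image_volume(array(0, c(10, 10, 4)), c(0, 0, 0), c(2, 2, 2), "CT")
  a3 <- mask_volume(a$voxels, g3); b3 <- mask_volume(b$voxels, g3)
  expect_equal(hd95(a3, b3), 2 * hd95(a, b), tolerance = 1e-9)

  e <- mask_from(integer(0))
  expect_warning(expect_true(is.na(hd95(e, a))), "empty")
})

test_that("metrics match brute-force oracles on random volumes", {
  set.seed(77)
  for (i in 1:20) {
    a <- random_mask(c(16, 16, 16), p = stats::runif(1, 0.1, 0.5))
    b <- random_mask(c(16, 16, 16), p = stats::runif(1, 0.1, 0.5))
    expect_equal(dice(a, b), dice_oracle(a, b), tolerance = 1e-12)
    expect_equal(jaccard(a, b), jaccard_oracle(a, b), tolerance = 1e-12)
    expect_equal(hd95(a, b), hd95_oracle(a, b), tolerance = 1e-9)
  }
})

test_that("effective length is the contoured axial extent", {
  circles <- lapply(seq(0, 45, by = 3), function(z) {
    tubseg:::circle_contour(0, 0, 5, z)
  })
  s <- structure_set(list(g = list(contours = circles)))
  expect_equal(effective_length(s), 45)
  one <- structure_set(list(g = list(contours = circles[1])))
  expect_equal(effective_length(one), 0)
  expect_error(effective_length(structure_set(list(g = list(contours =
    list())))), "no contours")
})

test_that("effective radius is the 90th percentile equivalent-circle radius", {
  # all slices area 25*pi -> radius exactly 5
  circles <- lapply(seq(0, 12, by = 3), function(z) {
    tubseg:::circle_contour(0, 0, 5, z, n = 256L)
  })
  s <- structure_set(list(g = list(contours = circles)))
  expect_equal(effective_radius(s), 5, tolerance = 1e-3)

  one <- structure_set(list(g = list(contours = circles[1])))
  expect_equal(effective_radius(one), 5, tolerance = 1e-3)

  # radii 1..10: compare against an independent sort-and-interpolate oracle
  mixed <- structure_set(list(g = list(contours = lapply(1:10, function(r) {
    tubseg:::circle_contour(0, 0, r, 3 * r, n = 512L)
  }))))
  radii <- 1:10
  h <- (10 - 1) * 0.9 + 1
  oracle <- radii[floor(h)] + (h - floor(h)) * (radii[ceiling(h)] - radii[floor(h)])
  expect_equal(effective_radius(mixed), oracle, tolerance = 1e-3)

  # two polygons on one slice sum their areas
  twin <- structure_set(list(g = list(contours = list(
    tubseg:::circle_contour(-10, 0, 3, 0, n = 256L),
    tubseg:::circle_contour(10, 0, 4, 0, n = 256L)))))
  expect_equal(effective_radius(twin), 5, tolerance = 1e-2)
})

test_that("paired t-test matches its closed form and flags degeneracy", {
  r <- paired_t_test(c(2, 3, 4), c(1, 1, 1))   # differences 1, 2, 3
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(r$degenerate)

  # scaling all differences and their scatter equally leaves t unchanged
  r2 <- paired_t_test(2 * c(2, 3, 4), 2 * c(1, 1, 1))
  expect_equal(r2$t, r$t, tolerance = 1e-12)

  d <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_true(is.na(d$t) && is.na(d$p))
  expect_error(paired_t_test(1, c(1, 2)), "paired")
  expect_error(paired_t_test(1, 1), "two pairs")
})

test_that("fold aggregation averages within folds then across folds", {
  df <- data.frame(dsc = c(0.6, 0.6, 0.62, 0.62, 0.64, 0.64,
                           0.66, 0.66, 0.68, 0.68))
  folds <- rep(1:5, each = 2)
  agg <- aggregate_folds(df, folds)
  expect_equal(nrow(agg$fold_means), 5)
  expect_equal(agg$summary$mean[agg$summary$metric == "dsc"], 0.64)

  # identical metrics give zero cross-fold sd
  same <- data.frame(dsc = rep(0.5, 6), hd = rep(2, 6))
  agg2 <- aggregate_folds(same, rep(1:3, each = 2))
  expect_equal(agg2$summary$sd, c(0, 0))

  # permuting patients within folds leaves the summary unchanged
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  agg3 <- aggregate_folds(df[perm, , drop = FALSE], folds[perm])
  expect_equal(agg3$summary, agg$summary)
  expect_error(aggregate_folds(df, folds[-1]), "every row")
})
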