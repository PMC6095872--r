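test_that("resampling is the identity at the target spacing", {
  img <- test_image(rnorm(27), c(3, 3, 3), spacing = c(2, 2, 2))
  msk <- mask3d(array(TRUE, c(3, 3, 3)), c(2, 2, 2))
  rs <- resample_isotropic(img, msk, 2)
  expect_identical(rs$image$voxels, img$voxels)
  expect_identical(rs$mask$voxels, msk$voxels)
})

test_that("resampling preserves constant images for any spacing change", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      sp <- runif(3, 0.5, 4)
      t <- runif(1, 0.4, 3)
      d <- sample(3:7, 3, replace = TRUE)
    })
    img <- image3d(array(4.2, d), sp, "MR", "arbitrary")
    msk <- mask3d(array(TRUE, d), sp)
    rs <- resample_isotropic(img, msk, t)
    expect_true(all(abs(rs$image$voxels - 4.2) < 1e-12))
    expect_equal(rs$image$spacing, rep(t, 3))
  }
})

test_that("halving the spacing of a linear ramp interpolates midpoints", {
  img <- test_image(c(0, 1, 2, 3), c(4, 1, 1), spacing = c(2, 1, 1),
                    modality = "MR", units = "arbitrary")
  msk <- test_mask(4, c(4, 1, 1), spacing = c(2, 1, 1))
  rs <- resample_isotropic(img, msk, 1)
  expect_equal(as.numeric(rs$image$voxels), c(0, 0.5, 1, 1.5, 2, 2.5, 3))
})

test_that("resampling that empties the mask errors with the tumor id", {
  arr <- array(FALSE, c(9, 9, 9)); arr[2, 2, 2] <- TRUE
  img <- image3d(array(1, c(9, 9, 9)), c(1, 1, 1), "PET", "SUV")
  expect_error(
    resample_isotropic(img, mask3d(arr, c(1, 1, 1)), 4, tumor_id = "T042"),
    "T042")
})

test_that("SUV conversion matches hand arithmetic", {
  img <- test_image(rep(3.7, 8), c(2, 2, 2), units = "activity_conc_kBq_per_ml")
  expect_equal(unique(as.numeric(to_suv(img, 70000, 259000)$voxels)), 1)
  z <- test_image(rep(0, 8), c(2, 2, 2), units = "activity_conc_kBq_per_ml")
  expect_equal(unique(as.numeric(to_suv(z, 70000, 259000)$voxels)), 0)
  img2 <- test_image(rep(2, 8), c(2, 2, 2), units = "activity_conc_kBq_per_ml")
  suv <- to_suv(img2, 50000, 400000,
                injection_to_scan_min = 109.77, half_life_min = 109.77)
  expect_equal(unique(as.numeric(suv$voxels)), 0.5)
  expect_identical(suv$units, "SUV")
})

test_that("SUV is linear in activity and inversely linear in dose", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      c0 <- runif(1, 0.5, 10); w <- runif(1, 4e4, 9e4)
      a <- runif(1, 2e5, 5e5); delay <- runif(1, 0, 120)
    })
    base <- test_image(c0, c(1, 1, 1), units = "activity_conc_kBq_per_ml")
    doubled <- test_image(2 * c0, c(1, 1, 1), units = "activity_conc_kBq_per_ml")
    s1 <- to_suv(base, w, a, delay)$voxels[1]
    expect_equal(to_suv(doubled, w, a, delay)$voxels[1], 2 * s1)
    expect_equal(to_suv(base, w, 2 * a, delay)$voxels[1], s1 / 2)
  }
  img <- test_image(1, c(1, 1, 1), units = "activity_conc_kBq_per_ml")
  expect_error(to_suv(img, -1, 1000), "weight")
  expect_error(to_suv(img, 1000, 0), "activity")
})

test_that("discretization follows the floor-binning formula", {
  img <- test_image(c(0.05, 0.14, 0.26), c(3, 1, 1))
  msk <- test_mask(3, c(3, 1, 1))
  d <- discretize(img, msk, 0.1)
  expect_equal(as.integer(d$levels[1:3]), c(1L, 1L, 3L))
  expect_equal(d$Ng, 3L)

  const <- discretize(test_image(rep(2, 5), c(5, 1, 1)),
                      test_mask(5, c(5, 1, 1)), 0.25)
  expect_equal(const$Ng, 1L)
  expect_true(all(const$levels[1:5] == 1L))

  ramp <- discretize(test_image(seq(0, 0.95, by = 0.05), c(20, 1, 1)),
                     test_mask(20, c(20, 1, 1)), 0.1)
  expect_equal(ramp$Ng, 10L)
  expect_equal(as.integer(tabulate(ramp$levels[ramp$levels > 0])),
               rep(2L, 10))
})

test_that("discretization is shift-invariant and conserves voxel counts", {
  for (seed in 1:8) {
    fx <- random_discretized(seed)
    shifted <- image3d(fx$image$voxels + 17.3, fx$image$spacing,
                       fx$image$modality, fx$image$units)
    d2 <- discretize(shifted, fx$mask, fx$bin_width)
    expect_identical(fx$disc$levels, d2$levels)
    lev <- fx$disc$levels[fx$mask$voxels]
    expect_true(all(lev >= 1L))
    expect_equal(sum(tabulate(lev, fx$disc$Ng)), sum(fx$mask$voxels))
  }
})
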