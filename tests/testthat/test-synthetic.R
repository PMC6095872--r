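test_that("tumor volumes are reproducible from their seed", {
  gp <- list(pet_mean = 4, pet_sd = 0.5, mr_mean = 230, mr_sd = 28,
             corr_len = 1.5, semi_axes = c(8, 7, 6), noise_frac = 0.3,
             pet_spacing = 2, mr_spacing = 1, body_weight_g = 70000,
             injected_activity_kBq = 370000, delay_min = 60)
  v1 <- generate_tumor_volume(gp, seed = 21)
  v2 <- generate_tumor_volume(gp, seed = 21)
  expect_identical(v1$pet$voxels, v2$pet$voxels)
  expect_identical(v1$mr$voxels, v2$mr$voxels)
  v3 <- generate_tumor_volume(gp, seed = 22)
  expect_false(identical(v1$pet$voxels, v3$pet$voxels))
})

test_that("SUV conversion of a generated PET tumor recovers the target mean", {
  gp <- list(pet_mean = 4, pet_sd = 0.4, mr_mean = 230, mr_sd = 28,
             corr_len = 1, semi_axes = c(10, 9, 8), noise_frac = 0.3,
             pet_spacing = 2, mr_spacing = 1, body_weight_g = 70000,
             injected_activity_kBq = 370000, delay_min = 60)
  v <- generate_tumor_volume(gp, seed = 30)
  expect_identical(v$pet$units, "activity_conc_kBq_per_ml")
  suv <- to_suv(v$pet, 70000, 370000, injection_to_scan_min = 60)
  expect_lt(abs(mean(suv$voxels[v$pet_mask$voxels]) - 4), 0.3)
})

test_that("a spherical tumor has sphericity near 1 and sub-voxel axes error", {
  gp <- list(pet_mean = 4, pet_sd = 0.4, mr_mean = 230, mr_sd = 28,
             corr_len = 1, semi_axes = c(9, 9, 9), noise_frac = 0.3,
             pet_spacing = 2, mr_spacing = 1, body_weight_g = 70000,
             injected_activity_kBq = 370000, delay_min = 60)
  v <- generate_tumor_volume(gp, seed = 31)
  sf <- shape_features(v$mr_mask, "mesh")
  expect_lt(abs(sf$sphericity - 1), 0.03)
  gp$semi_axes <- c(0.5, 9, 9)
  expect_error(generate_tumor_volume(gp, seed = 31), "one voxel")
})

test_that("longer texture correlation raises GLCM homogeneity", {
  gp <- list(pet_mean = 4, pet_sd = 0.4, mr_mean = 230, mr_sd = 28,
             semi_axes = c(10, 9, 8), noise_frac = 0.3,
             pet_spacing = 2, mr_spacing = 1, body_weight_g = 70000,
             injected_activity_kBq = 370000, delay_min = 60)
  hom_at <- function(cl) {
    vals <- vapply(1:4, function(s) {
      v <- generate_tumor_volume(c(gp, corr_len = cl), seed = 100 + s)
      disc <- discretize(v$mr, v$mr_mask, 5.0)
      glcm_features(disc)$homogeneity1
    }, numeric(1))
    mean(vals)
  }
  h <- vapply(c(0.4, 1.5, 3.0), hom_at, numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("identity grade coupling forces perfect cluster-outcome association", {
  sp <- small_cohort_spec(seed = 41, n = 15)
  sp$grade_coupling <- diag(3)
  ch <- generate_cohort(sp)
  expect_equal(cramers_v_test(ch$truth$group, ch$clinical$grade)$cramers_v, 1)
})

test_that("degenerate outcome coupling is rejected", {
  sp <- small_cohort_spec(seed = 42, n = 12)
  sp$never_free_prob <- 0
  sp$rfs_coef <- c(intercept = -30, suv = 0, logvol = 0)
  expect_error(generate_cohort(sp), "degenerate")
})

test_that("the truth record reproduces recovery metrics without regeneration", {
  ch <- generate_cohort(small_cohort_spec(seed = 43, n = 12))
  expect_setequal(names(ch$truth),
                  c("tumor_id", "group", "suv_mean_true", "mr_mean_true",
                    "corr_len", "volume_true", "eta", "tumor_seed"))
  expect_equal(nrow(ch$truth), 12)
  expect_identical(ch$truth$tumor_id, ch$manifest$tumor_id)
  # clinical labels line up with the truth groups it was sampled from
  expect_equal(length(unique(ch$truth$group)), 3L)
  ch2 <- generate_cohort(small_cohort_spec(seed = 43, n = 12))
  expect_identical(ch$truth, ch2$truth)
  expect_identical(ch$clinical, ch2$clinical)
})

test_that("wider planted SUV separation strengthens the feature-outcome link", {
  rho_at <- function(gap, seed) {
    sp <- cohort_spec(seed = seed, n_tumors = 24,
                      pet_mean = 4 + c(-gap, 0, gap) / 2,
                      semi_axes = rbind(c(7, 6, 6), c(8, 7, 6), c(9, 8, 7)),
                      grade_coupling = diag(3))
    ch <- generate_cohort(sp)
    fx <- extract_cohort_features(ch$manifest, mr_spacing = 1.0)
    abs(spearman_assoc(fx["PET_mean"], ch$clinical$grade)$rho)
  }
  weak <- mean(vapply(1:3, function(s) rho_at(0.5, 50 + s), numeric(1)))
  strong <- mean(vapply(1:3, function(s) rho_at(4, 50 + s), numeric(1)))
  expect_gt(strong, weak)
  expect_gt(strong, 0.9)
})
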