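test_that("degenerate phantom specs are rejected", {
  expect_error(phantom_spec(region_radii = c(4, 8, 12)), class = "attnseg_validation_error")
  expect_error(phantom_spec(region_radii = c(8, 8, 4)), class = "attnseg_validation_error")
  expect_error(phantom_spec(region_radii = c(8, 4, -1)), class = "attnseg_validation_error")
  expect_error(phantom_spec(noise_sd = -1), class = "attnseg_validation_error")
  # largest sphere must fit inside the brain ellipsoid (z semi-axis 7.2 here)
  expect_error(phantom_spec(grid_shape = c(96, 96, 16), region_radii = c(20, 13, 7)),
               class = "attnseg_validation_error")
})

test_that("zero-noise phantom renders exact tissue means", {
  cs <- generate_phantom(small_spec(noise_sd = 0))
  tm <- default_tissue_means()
  for (m in seq_len(4)) {
    vol <- cs$modalities[[m]]
    for (cls in 0:3) {
      vox <- vol[cs$mask == cls & vol != 0]
      if (length(vox)) expect_true(all(vox == tm[m, cls + 1]))
    }
  }
  # voxels outside the brain are exactly zero
  expect_true(any(cs$modalities$t1 == 0))
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom(small_spec(seed = 7L))
  b <- generate_phantom(small_spec(seed = 7L))
  expect_identical(a$modalities, b$modalities)
  expect_identical(a$mask, b$mask)
  c <- generate_phantom(small_spec(seed = 8L))
  expect_false(identical(a$modalities$t1, c$modalities$t1))
})

test_that("label counts match the analytic sphere oracle for radii (12,8,4)", {
  sp <- phantom_spec(grid_shape = c(48L, 48L, 48L), region_radii = c(12, 8, 4),
                     noise_sd = 0, seed = 1L)
  cs <- generate_phantom(sp)
  ctr <- sp$tumor_center
  n_whole <- sphere_count(sp$grid_shape, ctr, 12)
  n_core <- sphere_count(sp$grid_shape, ctr, 8)
  n_enh <- sphere_count(sp$grid_shape, ctr, 4)
  expect_gt(sum(cs$mask == 1L), 0)
  expect_gt(sum(cs$mask == 2L), 0)
  expect_gt(sum(cs$mask == 3L), 0)
  expect_identical(sum(cs$mask == 3L), n_enh)
  expect_identical(sum(cs$mask %in% c(1L, 3L)), n_core)
  expect_identical(sum(cs$mask > 0L), n_whole)
  expect_lt(sum(cs$mask == 3L), sum(cs$mask %in% c(1L, 3L)))
  expect_lt(sum(cs$mask %in% c(1L, 3L)), sum(cs$mask > 0L))
})

test_that("required modality contrasts hold in the default tissue means", {
  tm <- default_tissue_means()
  expect_gt(tm["flair", "edema"], tm["flair", "healthy"])
  expect_gt(tm["t1ce", "enhancing"], tm["t1ce", "core"])
})

test_that("region nesting holds on every cohort case", {
  cases <- phantom_cohort(4, small_spec(), seed = 3L)
  for (cs in cases) {
    rm <- region_masks(cs$mask)
    expect_true(all(rm$ET[rm$ET] & rm$TC[rm$ET]))   # ET subset TC
    expect_true(all(rm$WT[rm$TC]))                  # TC subset WT
  }
})

test_that("mean region intensity converges to the tissue mean", {
  sd0 <- 1
  cs <- generate_phantom(small_spec(noise_sd = sd0, seed = 9L))
  tm <- default_tissue_means()
  for (cls in 1:3) {
    vox <- cs$modalities$t2[cs$mask == cls]
    tol <- 3 * sd0 / sqrt(length(vox))
    expect_lt(abs(mean(vox) - tm["t2", cls + 1]), tol)
  }
})

test_that("phantom_cohort jitters geometry reproducibly", {
  expect_error(phantom_cohort(0), class = "attnseg_validation_error")
  a <- phantom_cohort(5, small_spec(), seed = 5L)
  b <- phantom_cohort(5, small_spec(), seed = 5L)
  expect_identical(lapply(a, `[[`, "mask"), lapply(b, `[[`, "mask"))
  # pairwise-distinct tumor centers: compare enhancing-region centroids
  cents <- vapply(a, function(cs) {
    w <- which(cs$mask == 3L, arr.ind = TRUE)
    colMeans(w)
  }, numeric(3))
  expect_identical(nrow(unique(t(cents))), 5L)
  one <- phantom_cohort(1, small_spec(), seed = 5L)
  expect_s3_class(one[[1]], "case_bundle")
})
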