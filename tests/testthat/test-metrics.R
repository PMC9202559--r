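test_that("region composites follow the BraTS nesting convention", {
  z <- array(0L, dim = c(4, 4, 2))
  r <- region_masks(z)
  expect_false(any(r$ET) || any(r$TC) || any(r$WT))
  one <- z; one[2, 2, 1] <- 3L
  r <- region_masks(one)
  expect_true(r$ET[2, 2, 1] && r$TC[2, 2, 1] && r$WT[2, 2, 1])
  expect_identical(sum(r$ET), 1L)
  expect_error(region_masks(array(4L, dim = c(2, 2, 1))),
               class = "attnseg_validation_error")
})

test_that("phantom region sizes match the analytic sphere enumeration", {
  sp <- phantom_spec(grid_shape = c(48L, 48L, 48L), region_radii = c(12, 8, 4),
                     noise_sd = 0, seed = 1L)
  cs <- generate_phantom(sp)
  r <- region_masks(cs$mask)
  ctr <- sp$tumor_center
  expect_identical(sum(r$ET), sphere_count(sp$grid_shape, ctr, 4))
  expect_identical(sum(r$TC), sphere_count(sp$grid_shape, ctr, 8))
  expect_identical(sum(r$WT), sphere_count(sp$grid_shape, ctr, 12))
  expect_lt(sum(r$ET), sum(r$TC)); expect_lt(sum(r$TC), sum(r$WT))
})

test_that("dsc matches its definition and conventions", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE          # |A| = 4
  b <- matrix(FALSE, 4, 4); b[1:3, 1:2] <- TRUE
  b[2, 2] <- FALSE; b[4, 1] <- TRUE                       # |B| = 6, overlap 3
  expect_identical(sum(a & b), 3L)
  expect_equal(dsc(a, b), 2 * 3 / (4 + 6))                # 0.6, hand arithmetic
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, !a), 0)                             # disjoint
  expect_equal(dsc(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)  # empty-empty
  expect_equal(dsc(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2)), 0)
  expect_error(dsc(a, matrix(TRUE, 2, 2)), class = "attnseg_contract_error")
})

test_that("set-overlap and confusion-count DSC formulas agree (200 trials)", {
  set.seed(40)
  for (t in 1:200) {
    n <- sample(4:30, 1)
    a <- matrix(runif(n * n) < runif(1), n, n)
    b <- matrix(runif(n * n) < runif(1), n, n)
    cm <- confusion_metrics(a, b)
    expect_equal(dsc(a, b), cm$dsc)
    expect_equal(dsc(a, b), dsc(b, a))                    # symmetry
  }
})

test_that("dsc grows with the intersection at fixed mask sizes", {
  a <- matrix(FALSE, 6, 6); a[1:3, 1:4] <- TRUE
  prev <- -1
  for (k in 0:3) {
    b <- matrix(FALSE, 6, 6)
    if (k > 0) b[1:k, 1:4] <- TRUE                        # k rows overlap
    if (k < 3) b[(4:6)[seq_len(3 - k)], 1:4] <- TRUE      # filler rows
    val <- dsc(a, b)
    expect_gt(val, prev)
    prev <- val
  }
})

test_that("confusion metrics match direct counts and report NA on empty denominators", {
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$accuracy, 1)
  allpos <- confusion_metrics(matrix(TRUE, 2, 2), truth)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$accuracy, 0.5)
  none <- confusion_metrics(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2))
  expect_true(is.na(none$sensitivity))                    # TP+FN = 0
  expect_true(is.na(none$precision))
  expect_equal(none$accuracy, 1)
  cm <- confusion_metrics(allpos <- matrix(TRUE, 2, 2), truth)
  expect_identical(sum(cm$counts), 4L)
})

test_that("corrupting only ET voxels leaves the WT comparison untouched", {
  cs <- generate_phantom(small_spec(noise_sd = 0))
  pred <- cs$mask
  pred[pred == 3L] <- 1L                 # ET voxels relabeled inside the core
  rp <- region_masks(pred); rt <- region_masks(cs$mask)
  expect_identical(sum(rp$WT), sum(rt$WT))
  expect_equal(dsc(rp$WT, rt$WT), 1)
  expect_equal(dsc(rp$ET, rt$ET), 0)
})

test_that("metrics_report emits one row per region with values in [0,1]", {
  cs <- generate_phantom(small_spec())
  rep <- metrics_report(cs$mask, cs$mask)
  expect_identical(rep$region, c("ET", "TC", "WT"))
  expect_true(all(rep$dsc == 1))
  num <- unlist(rep[, -1])
  expect_true(all(is.na(num) | (num >= 0 & num <= 1)))
})
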