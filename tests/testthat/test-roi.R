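test_that("mirroring is an index reversal and an involution", {
  m <- array(FALSE, dim = c(48, 10, 6))
  m[4, 6, 3] <- TRUE  # 0-based (3, 5, 2)
  mm <- mirror_mask(roi_mask(m))
  expect_equal(which(mm$data, arr.ind = TRUE) - 1L,
               matrix(c(44L, 5L, 2L), 1, dimnames = NULL),
               ignore_attr = TRUE)
  expect_identical(mirror_mask(mm)$data, m)
  expect_equal(mask_size(mm), 1L)

  sym <- array(FALSE, dim = c(8, 4, 4))
  sym[c(2, 7), 2, 2] <- TRUE
  expect_identical(mirror_mask(roi_mask(sym))$data, sym)
})

test_that("rater intersection keeps the consensus and rejects disagreement", {
  a <- array(FALSE, c(10, 10, 4)); b <- a
  a[1:10] <- TRUE          # 10 voxels
  b[5:12] <- TRUE          # 8 voxels, 6 shared
  inter <- intersect_rater_masks(roi_mask(a), roi_mask(b))
  expect_equal(mask_size(inter), 6L)
  expect_identical(which(inter$data), 5:10)
  expect_identical(intersect_rater_masks(roi_mask(a), roi_mask(a))$data, a)
  disj <- array(FALSE, c(10, 10, 4)); disj[90:95] <- TRUE
  expect_error(intersect_rater_masks(roi_mask(a), roi_mask(disj)),
               "empty intersection")
})

test_that("hemisphere masks split symmetric brains evenly and exclude the midline", {
  sub <- small_symmetric_subject()
  brain <- sub$field$brain_mask
  left <- hemisphere_mask(brain, "left")
  right <- hemisphere_mask(brain, "right")
  expect_equal(mask_size(left), mask_size(right))
  expect_equal(mask_size(left) + mask_size(right), mask_size(brain))
  expect_identical(mirror_mask(left)$data, right$data)
  expect_equal(sum(left$data & right$data), 0L)
  # a hemisphere target never intersects its own mirror
  expect_equal(sum(left$data & mirror_mask(left)$data), 0L)

  # odd grid width: midline column in neither hemisphere
  ob <- roi_mask(array(TRUE, c(9, 4, 4)))
  lo <- hemisphere_mask(ob, "left"); ro <- hemisphere_mask(ob, "right")
  expect_equal(mask_size(lo), 4L * 4L * 4L)
  expect_equal(sum(lo$data[5, , ] | ro$data[5, , ]), 0L)
})

test_that("difference maps are antisymmetric and zero for symmetric images", {
  sub <- small_symmetric_subject()
  m <- mean_over_gradients(sub$dwi)
  d0 <- difference_map(m, sub$field$brain_mask)
  expect_true(all(d0 == 0))

  m[3, 12, 5] <- m[3, 12, 5] + 20   # mirror voxel is (22, 12, 5) 1-based
  d <- difference_map(m, sub$field$brain_mask)
  expect_equal(d[3, 12, 5], 20)
  expect_equal(d[22, 12, 5], -20)
  expect_equal(d, -d[24:1, , , drop = FALSE][, , , drop = TRUE],
               ignore_attr = TRUE)
})

test_that("threshold derivation finds the equal-variance Gaussian crossing", {
  mk <- function(vals) {
    n <- length(vals)
    dims <- c(n, 1, 1)
    list(diff_map = array(vals, dims),
         target = roi_mask(array(TRUE, dims)))
  }
  set.seed(31)
  refs <- list(normal = mk(rnorm(4000, 0, 2)),
               acute = mk(rnorm(4000, 10, 2)),
               sequela = mk(rnorm(4000, -10, 2)))
  thr <- derive_thresholds(refs)
  # equal-variance Gaussians cross at the midpoint of their means
  expect_lt(abs(thr$t1 - (-5)), 1)
  expect_lt(abs(thr$t2 - 5), 1)
  expect_lt(thr$t1, thr$t2)

  # identical class distributions force the degenerate fallback path
  set.seed(32)
  same <- rnorm(500)
  w <- capture_warnings(
    thr_deg <- derive_thresholds(list(normal = mk(same), acute = mk(same),
                                      sequela = mk(same))))
  expect_true(any(grepl("midpoint", w)))
  expect_true(is.finite(thr_deg$t1) && is.finite(thr_deg$t2))
  expect_lte(thr_deg$t1, thr_deg$t2)
  expect_error(derive_thresholds(list(normal = mk(same), acute = mk(same))),
               "sequela")
})

test_that("phantom-calibrated thresholds bracket zero", {
  thr <- default_test_thresholds()
  expect_lt(thr$t1, 0)
  expect_gt(thr$t2, 0)
})

test_that("semiautomatic segmentation recovers acute phantom lesions", {
  cohort <- default_test_cohort()
  thr <- default_test_thresholds()
  s <- cohort[[10]]  # acute, not a calibration reference
  seg <- segment_semiauto(mean_over_gradients(gaussian_smooth(s$dwi, 3)),
                          s$brain_mask, thr)
  expect_equal(seg$lesion_kind, "acute")
  expect_gte(dice(seg$roi$data, s$truth_lesion$data), 0.5)

  # output stays within the brain and within one hemisphere
  expect_true(all(s$brain_mask$data[seg$roi$data]))
  nx <- dim(seg$roi$data)[1]
  xs <- which(seg$roi$data, arr.ind = TRUE)[, 1] - 1L
  expect_true(all(xs < (nx - 1) / 2) || all(xs > (nx - 1) / 2))
})

test_that("symmetric or unthresholdable inputs yield a flagged empty result", {
  sub <- small_symmetric_subject()
  thr <- structure(list(t1 = -10, t2 = 10,
                        class_means = c(sequela = -1, normal = 0, acute = 1)),
                   class = "threshold_pair")
  seg <- segment_semiauto(mean_over_gradients(sub$dwi),
                          sub$field$brain_mask, thr)
  expect_equal(seg$lesion_kind, "no-lesion")
  expect_equal(mask_size(seg$roi), 0L)

  inf_thr <- structure(list(t1 = -Inf, t2 = Inf), class = "threshold_pair")
  noisy <- add_rician_noise(sub$dwi, 20, seed = 2)
  seg2 <- segment_semiauto(mean_over_gradients(noisy),
                           sub$field$brain_mask, inf_thr)
  expect_equal(seg2$lesion_kind, "no-lesion")
  expect_equal(mask_size(seg2$roi), 0L)
})

test_that("largest_component labels under 26-connectivity", {
  m <- array(FALSE, c(8, 8, 3))
  m[1:2, 1:2, 1] <- TRUE            # 4-voxel block
  m[4, 4, 2] <- TRUE                # diagonal neighbour of (3,3,1)... isolated
  m[6:8, 6, 3] <- TRUE              # 3-voxel line
  comp <- largest_component(m)
  expect_equal(sum(comp), 4L)
  expect_true(all(comp[1:2, 1:2, 1]))
  # diagonal touch merges under 26-connectivity
  m2 <- array(FALSE, c(4, 4, 2))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(sum(largest_component(m2)), 2L)
})
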