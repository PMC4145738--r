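test_that("lesion-free tensor fields are exactly mirror-symmetric", {
  field <- make_tensor_field(c(24, 24, 10), c(1, 1, 5))
  flipped <- field$D[24:1, , , , drop = FALSE]
  expect_identical(field$D, flipped)
  expect_identical(field$brain_mask$data,
                   field$brain_mask$data[24:1, , , drop = FALSE])
})

test_that("lesions rescale mean diffusivity by adc_scale and stay lateralized", {
  les <- lesion_spec(c(6, 12, 5), radius = 5, kind = "acute", adc_scale = 0.6)
  field <- make_tensor_field(c(24, 24, 10), c(1, 1, 5), lesions = list(les))
  ref <- make_tensor_field(c(24, 24, 10), c(1, 1, 5))
  inside <- field$lesion_masks[[1]]$data
  md <- (field$D[, , , 1] + field$D[, , , 2] + field$D[, , , 3]) / 3
  md_ref <- (ref$D[, , , 1] + ref$D[, , , 2] + ref$D[, , , 3]) / 3
  expect_equal(md[inside], 0.6 * md_ref[inside], tolerance = 1e-9)

  # two disjoint lesions yield disjoint truth masks
  l2 <- lesion_spec(c(6, 12, 2), 4, "sequela")
  l3 <- lesion_spec(c(6, 12, 8), 4, "acute")
  f2 <- make_tensor_field(c(24, 24, 10), c(1, 1, 5), lesions = list(l2, l3))
  expect_equal(sum(f2$lesion_masks[[1]]$data & f2$lesion_masks[[2]]$data), 0L)

  # a lesion crossing the midplane would corrupt its own mirror reference
  expect_error(
    make_tensor_field(c(24, 24, 10), c(1, 1, 5),
                      lesions = list(lesion_spec(c(11, 12, 5), 5, "acute"))),
    "midplane")
  expect_error(lesion_spec(c(6, 12, 5), 5, "acute", adc_scale = 1.2),
               "adc_scale < 1")
  expect_error(lesion_spec(c(6, 12, 5), 5, "sequela", adc_scale = 0.9),
               "adc_scale > 1")
})

test_that("the signal model reproduces its closed forms", {
  sub <- small_symmetric_subject()
  img <- sub$dwi
  brain <- sub$field$brain_mask$data
  # b = 0 volume equals s0 on every brain voxel, 0 outside
  b0 <- img$data[, , , 1]
  expect_true(all(b0[brain] == 1000))
  expect_true(all(b0[!brain] == 0))

  # isotropic D = 1e-3, b = 1000: S = s0 * exp(-1) in every direction
  shape <- c(16, 16, 8)
  iso <- make_tensor_field(shape, c(1, 1, 5), base_md = 1e-3, base_fa = 0)
  # flatten the FA ramp by forcing an isotropic tensor directly
  iso$D[, , , 1:3][array(rep(iso$brain_mask$data, 3), c(shape, 3))] <- 1e-3
  iso$D[, , , 4:6] <- 0
  sig <- simulate_signal(iso, s0 = 1000, scheme = small_scheme(6))
  dw <- sig$data[, , , 2:7]
  msk <- array(rep(iso$brain_mask$data, 6), dim = c(shape, 6))
  expect_equal(unique(round(dw[msk], 9)), round(1000 * exp(-1), 9))

  # zero tensor (outside brain) stays 0 in every volume; s0 must be positive
  expect_true(all(sig$data[array(rep(!iso$brain_mask$data, 7),
                                 c(shape, 7))] == 0))
  expect_error(simulate_signal(iso, s0 = 0), "positive")
})

test_that("Rician noise is deterministic, unbiased at sigma 0, Rayleigh at S = 0", {
  sub <- small_symmetric_subject()
  img <- sub$dwi
  expect_identical(add_rician_noise(img, 0, seed = 5), img)
  n1 <- add_rician_noise(img, 10, seed = 7)
  n2 <- add_rician_noise(img, 10, seed = 7)
  expect_identical(n1$data, n2$data)
  expect_false(identical(n1$data, add_rician_noise(img, 10, seed = 8)$data))

  # S = 0 with sigma = 1 gives a Rayleigh magnitude, mean sqrt(pi/2)
  zero <- dwi_image(array(0, dim = c(30, 30, 20, 2)), c(1, 1, 1),
                    small_scheme(1))
  noisy <- add_rician_noise(zero, 1, seed = 11)
  n <- length(noisy$data)
  se <- sqrt((4 - pi) / 2) / sqrt(n)
  expect_lt(abs(mean(noisy$data) - sqrt(pi / 2)), 3 * se)
})

test_that("signal inside a lesion rises monotonically as adc_scale falls", {
  mean_dw_lesion <- function(adc) {
    kind <- if (adc < 1) "acute" else "sequela"
    les <- lesion_spec(c(6, 12, 5), 5, kind, adc_scale = adc)
    f <- make_tensor_field(c(24, 24, 10), c(1, 1, 5), lesions = list(les))
    img <- simulate_signal(f, 1000, scheme = small_scheme(6))
    m <- mean_over_gradients(img)
    mean(m[f$lesion_masks[[1]]$data])
  }
  vals <- vapply(c(0.4, 0.6, 0.9, 1.3, 1.8), mean_dw_lesion, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("cohorts are deterministic with the requested composition", {
  cohort <- default_test_cohort()
  expect_length(cohort, 19L)
  classes <- vapply(cohort, `[[`, integer(1), "class")
  expect_equal(as.integer(table(classes)), c(8L, 8L, 3L))
  # normals carry no lesion, patients a nonempty lateralized one
  for (s in cohort) {
    if (s$class == 1L) {
      expect_equal(mask_size(s$truth_lesion), 0L)
    } else {
      expect_gt(mask_size(s$truth_lesion), 0L)
      expect_true(all(s$truth_lesion$data[s$brain_mask$data == FALSE] == FALSE))
    }
  }
  # same master seed, voxelwise identical images; lesion centers jittered
  small1 <- make_cohort(1, 2, 0, master_seed = 7,
                        params = modifyList(default_phantom_params(),
                                            list(shape = c(24L, 24L, 10L), lesion_radius = 5)))
  small2 <- make_cohort(1, 2, 0, master_seed = 7,
                        params = modifyList(default_phantom_params(),
                                            list(shape = c(24L, 24L, 10L), lesion_radius = 5)))
  expect_identical(small1[[2]]$dwi$data, small2[[2]]$dwi$data)
  expect_identical(small1[[1]]$truth_lesion$data == FALSE,
                   array(TRUE, c(24, 24, 10)))
  centers <- vapply(default_test_cohort()[9:16],
                    function(s) paste(s$lesion$center, collapse = ","),
                    character(1))
  expect_gt(length(unique(centers)), 1L)
})

test_that("written cohorts reload identically and ship a manifest", {
  d <- withr::local_tempdir()
  cohort <- make_cohort(1, 1, 0, master_seed = 3,
                        params = modifyList(default_phantom_params(),
                                            list(shape = c(24L, 24L, 10L), lesion_radius = 5)))
  manifest <- write_cohort(cohort, d)
  expect_equal(nrow(manifest), 2L)
  expect_error(write_cohort(cohort, d), "not empty")
  back <- read_dwi(file.path(d, "sub-02_dwi.nii.gz"),
                   file.path(d, "sub-02.bval"), file.path(d, "sub-02.bvec"))
  expect_identical(back$data, cohort[[2]]$dwi$data)
  lesion <- read_mask(file.path(d, "sub-02_lesion.nii.gz"), c(24, 24, 10))
  expect_identical(lesion$data, cohort[[2]]$truth_lesion$data)
})
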