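test_that("log-linear fitting recovers noiseless phantom tensors exactly", {
  les <- lesion_spec(c(6, 12, 5), 5, "acute")
  field <- make_tensor_field(c(24, 24, 10), c(1, 1, 5), lesions = list(les))
  img <- simulate_signal(field, s0 = 1000)
  fit <- fit_tensor(img, field$brain_mask)
  expect_lt(max(abs(fit$D - field$D)), 1e-6)
  expect_equal(attr(fit, "skipped"), 0L)

  # isotropic voxel: recovered trace/3 equals the set mean diffusivity
  lam <- tensor_eigenvalues(matrix(fit$D, ncol = 6))
  brain <- which(field$brain_mask$data)
  md_fit <- rowMeans(lam)[brain]
  md_true <- rowMeans(tensor_eigenvalues(matrix(field$D, ncol = 6)))[brain]
  expect_equal(md_fit, md_true, tolerance = 1e-9)

  # fewer than 6 distinct directions cannot determine the tensor
  img5 <- dwi_image(img$data[, , , 1:6], img$voxel_size, small_scheme(5))
  expect_error(fit_tensor(img5, field$brain_mask), "6 distinct")
})

test_that("closed-form eigenvalues agree with eigen() on random tensors", {
  set.seed(17)
  for (i in 1:50) {
    M <- crossprod(matrix(rnorm(9), 3))
    comp <- c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
    expect_equal(as.numeric(tensor_eigenvalues(comp)),
                 eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 tolerance = 1e-9)
  }
})

test_that("FA attains its closed-form limits and values", {
  mkfield <- function(l1, l2, l3) {
    D <- array(0, dim = c(2, 2, 2, 6))
    D[, , , 1] <- l1; D[, , , 2] <- l2; D[, , , 3] <- l3
    structure(list(D = D, brain_mask = roi_mask(array(TRUE, c(2, 2, 2))),
                   lesion_masks = list(), voxel_size = c(1, 1, 1)),
              class = "tensor_field")
  }
  expect_equal(unique(as.vector(fa_map(mkfield(1e-3, 1e-3, 1e-3)))), 0)
  expect_equal(unique(as.vector(fa_map(mkfield(1e-3, 0, 0)))), 1)
  # independent oracle: evaluate the eigenvalue formula directly
  lam <- c(1.7e-3, 0.3e-3, 0.3e-3)
  fa_ref <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(unique(as.vector(fa_map(mkfield(lam[1], lam[2], lam[3])))),
               fa_ref, tolerance = 1e-12)
  expect_equal(round(fa_ref, 4), 0.799)  # hand-checked magnitude
  # zero tensors map to FA 0, not NaN
  expect_equal(unique(as.vector(fa_map(mkfield(0, 0, 0)))), 0)
})

test_that("voxelwise FA test holds its false-positive rate under the null", {
  mkfa <- function(seed) {
    set.seed(seed)
    array(0.3 + rnorm(24 * 24 * 8, sd = 0.02), dim = c(24, 24, 8))
  }
  roi <- segment_auto_voxelwise(lapply(1:8, mkfa), lapply(101:108, mkfa),
                                alpha = 0.005)
  n_tested <- attr(roi, "n_tested")
  expect_equal(n_tested, 24L * 24L * 8L)
  fp <- mask_size(roi)
  band <- 3 * sqrt(n_tested * 0.005 * 0.995)
  expect_lt(abs(fp - n_tested * 0.005), band)

  # alpha = 1 returns every tested voxel
  all_roi <- segment_auto_voxelwise(lapply(1:3, mkfa), lapply(11:13, mkfa),
                                    alpha = 1)
  expect_equal(mask_size(all_roi), n_tested)
  expect_error(segment_auto_voxelwise(list(mkfa(1)), list(mkfa(2), mkfa(3))),
               "at least 2")
})

test_that("a strong FA drop is detected in most lesion voxels", {
  les <- lesion_spec(c(8, 16, 5), 5, "acute", adc_scale = 0.6, fa_scale = 0.3)
  shape <- c(32, 32, 10)
  lesion_field <- make_tensor_field(shape, c(1, 1, 5), lesions = list(les))
  normal_field <- make_tensor_field(shape, c(1, 1, 5))
  fa_of <- function(field, seed) {
    d <- add_rician_noise(simulate_signal(field, 1000), 20, seed = seed)
    fa_map(fit_tensor(gaussian_smooth(d, 3), field$brain_mask))
  }
  patients <- lapply(1:8, function(i) fa_of(lesion_field, i))
  controls <- lapply(11:18, function(i) fa_of(normal_field, i))
  roi <- segment_auto_voxelwise(patients, controls, alpha = 0.005)
  truth <- lesion_field$lesion_masks[[1]]
  hit <- sum(roi$data & truth$data) / mask_size(truth)
  expect_gte(hit, 0.8)
})
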