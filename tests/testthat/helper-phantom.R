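# Shared fixtures, built in code. The default 8/8/3 cohort takes a few
# seconds, so it is memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

default_test_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- make_cohort(8, 8, 3, master_seed = 42)
  }
  .fixture_cache$cohort
}

# Small noiseless symmetric subject (no lesion) on a quick grid.
small_symmetric_subject <- function() {
  if (is.null(.fixture_cache$sym)) {
    field <- make_tensor_field(c(24, 24, 10), c(1, 1, 5))
    .fixture_cache$sym <- list(field = field,
                               dwi = simulate_signal(field, s0 = 1000))
  }
  .fixture_cache$sym
}

# A small scheme with enough directions for a tensor fit: 1 b0 + the first
# n directions of the default scheme.
small_scheme <- function(n_dir = 8) {
  full <- default_gradient_scheme()
  gradient_scheme(full$bvals[1:(n_dir + 1)],
                  full$bvecs[, 1:(n_dir + 1), drop = FALSE],
                  order_tag = "test-subset")
}

# Semiauto thresholds calibrated on the default cohort's first subject of
# each class (memoized; ~4 s on first use).
default_test_thresholds <- function() {
  if (is.null(.fixture_cache$thresholds)) {
    cohort <- default_test_cohort()
    classes <- vapply(cohort, `[[`, integer(1), "class")
    refs <- lapply(c(normal = 1L, acute = 2L, sequela = 3L), function(cl) {
      s <- cohort[[which(classes == cl)[1]]]
      sm <- gaussian_smooth(s$dwi, 3)
      tg <- if (mask_size(s$truth_lesion) > 0) s$truth_lesion else
        hemisphere_mask(s$brain_mask, "left")
      list(diff_map = difference_map(mean_over_gradients(sm), s$brain_mask),
           target = tg)
    })
    .fixture_cache$thresholds <- derive_thresholds(refs)
  }
  .fixture_cache$thresholds
}

# Dice overlap of two logical arrays.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Canonical form of a partition: relabel clusters by order of first
# appearance, so two labelings describe the same partition iff their
# canonical forms are identical.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# Exhaustive K-means oracle: minimum WCSS over all assignments of n points
# to at most k non-empty clusters (Euclidean, centroid = mean).
brute_force_wcss <- function(x, k) {
  n <- nrow(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    w <- 0
    for (j in unique(lab)) {
      m <- x[lab == j, , drop = FALSE]
      w <- w + sum(sweep(m, 2, colMeans(m))^2)
    }
    if (w < best) best <- w
  }
  best
}
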