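#' Gaussian smoothing of a DWI image
#'
#' Convolves every 3D volume independently with an isotropic Gaussian of full
#' width at half maximum `fwhm_mm`, the standard neuroimaging smoothing step.
#' The kernel standard deviation is `fwhm_mm / sqrt(8 * ln 2)` in mm,
#' converted per axis into voxel units through the voxel size, so anisotropic
#' voxels (e.g. thick slices) receive proportionally narrower kernels along
#' that axis. Boundaries are handled by symmetric reflection, which conserves
#' the total image intensity for the normalized kernel.
#'
#' @param img a `dwi_image`.
#' @param fwhm_mm full width at half maximum in mm, >= 0; 0 is the identity.
#' @return a smoothed `dwi_image`.
#' @export
gaussian_smooth <- function(img, fwhm_mm = 3) {
  stopifnot(inherits(img, "dwi_image"))
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(img)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  sigma_vox <- sigma_mm / img$voxel_size
  out <- img$data
  for (axis in 1:3) {
    out <- .smooth_axis(out, axis, sigma_vox[axis])
  }
  dwi_image(pmax(out, 0), img$voxel_size, img$scheme)
}

# 1D Gaussian convolution along one spatial axis of a 4D array, symmetric
# (edge-repeating) reflection at the boundaries. The kernel is truncated at
# 4 sigma and renormalized, so it sums to 1 exactly and reflection conserves
# the grid total.
.smooth_axis <- function(a, axis, sigma) {
  if (sigma < 1e-8) return(a)
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  n <- dim(a)[axis]
  out <- array(0, dim = dim(a))
  for (k in -r:r) {
    idx <- seq_len(n) + k
    idx[idx < 1L] <- 1L - idx[idx < 1L]        # reflect below: 0 -> 1, -1 -> 2
    idx[idx > n] <- 2L * n + 1L - idx[idx > n] # reflect above
    shifted <- switch(axis,
                      a[idx, , , , drop = FALSE],
                      a[, idx, , , drop = FALSE],
                      a[, , idx, , drop = FALSE])
    out <- out + w[k + r + 1L] * shifted
  }
  out
}

#' Average the diffusion-weighted volumes of a subject
#'
#' Voxelwise arithmetic mean over the selected volumes, producing the single
#' mean DWI image per subject on which the mirror-difference segmentation
#' operates. By default only the 20 b > 0 volumes enter the mean; the b = 0
#' reference is excluded.
#'
#' @param img a `dwi_image`.
#' @param include_b0 also include b = 0 volumes in the mean.
#' @return a 3D array (same spatial grid as `img`).
#' @export
mean_over_gradients <- function(img, include_b0 = FALSE) {
  stopifnot(inherits(img, "dwi_image"))
  sel <- if (include_b0) seq_len(n_volumes(img$scheme)) else
    which(img$scheme$bvals > 0)
  if (!length(sel)) stop("no volumes selected for averaging", call. = FALSE)
  sp <- grid_shape(img)
  m <- matrix(img$data, ncol = dim(img$data)[4])
  array(rowMeans(m[, sel, drop = FALSE]), dim = sp)
}
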