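#' Fit diffusion tensors by log-linear least squares
#'
#' Per-voxel ordinary least squares on `ln(S_i / S0) = -b_i g_i' D g_i` over
#' the diffusion-weighted volumes, with S0 the mean of the b = 0 volumes.
#' This is the classical linear tensor estimator; it is exact on noiseless
#' monoexponential data. Voxels inside the mask with any nonpositive signal
#' cannot be log-transformed and are skipped (zero tensor, counted in the
#' `skipped` attribute). Tensors whose eigenvalues come out negative (a noise
#' artefact) are projected back to the positive semidefinite cone by clipping
#' the offending eigenvalues at 0.
#'
#' @param img a `dwi_image` whose scheme has >= 6 distinct b > 0 directions
#'   and >= 1 b = 0 volume.
#' @param brain_mask an `roi_mask`; only masked voxels are fitted.
#' @return a `tensor_field` (see [make_tensor_field()]) with attribute
#'   `skipped` = number of masked voxels left unfitted.
#' @export
fit_tensor <- function(img, brain_mask) {
  stopifnot(inherits(img, "dwi_image"), inherits(brain_mask, "roi_mask"))
  check_same_grid(grid_shape(img), dim(brain_mask$data))
  bvals <- img$scheme$bvals
  dw <- which(bvals > 0)
  b0 <- which(bvals == 0)
  if (length(b0) < 1L) stop("scheme has no b = 0 volume", call. = FALSE)
  gd <- img$scheme$bvecs[, dw, drop = FALSE]
  if (nrow(unique(t(round(gd, 10)))) < 6L) {
    stop("tensor fit needs at least 6 distinct diffusion-weighted directions",
         call. = FALSE)
  }
  # design: rows b*[gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz]
  X <- t(vapply(seq_along(dw), function(j) {
    g <- gd[, j]
    bvals[dw[j]] * c(g[1]^2, g[2]^2, g[3]^2,
                     2 * g[1] * g[2], 2 * g[1] * g[3], 2 * g[2] * g[3])
  }, numeric(6)))
  if (qr(X)$rank < 6L) {
    stop("gradient directions do not span the 6 tensor components",
         call. = FALSE)
  }
  proj <- solve(crossprod(X), t(X))  # 6 x n_dw least-squares projector

  shape <- grid_shape(img)
  vox <- which(brain_mask$data)
  S <- matrix(img$data, ncol = dim(img$data)[4])[vox, , drop = FALSE]
  s0 <- rowMeans(S[, b0, drop = FALSE])
  Sd <- S[, dw, drop = FALSE]
  ok <- s0 > 0 & apply(Sd > 0, 1, all)
  Dfit <- matrix(0, nrow = length(vox), ncol = 6L)
  if (any(ok)) {
    Y <- log(s0[ok] / Sd[ok, , drop = FALSE])  # recycles s0 down columns
    Dfit[ok, ] <- t(proj %*% t(Y))
    Dfit[ok, ] <- .clip_negative_eigs(Dfit[ok, , drop = FALSE])
  }
  D <- array(0, dim = c(shape, 6L))
  for (k in 1:6) {
    vol <- array(0, dim = shape); vol[vox] <- Dfit[, k]
    D[, , , k] <- vol
  }
  out <- structure(list(D = D, brain_mask = brain_mask, lesion_masks = list(),
                        voxel_size = img$voxel_size),
                   class = "tensor_field")
  attr(out, "skipped") <- sum(!ok)
  out
}

# Eigenvalues of many symmetric 3x3 tensors at once (rows = Dxx, Dyy, Dzz,
# Dxy, Dxz, Dyz), by the trigonometric closed form. Returns an n x 3 matrix,
# descending.
tensor_eigenvalues <- function(comp) {
  comp <- matrix(comp, ncol = 6L)
  a <- comp[, 1]; b <- comp[, 2]; c <- comp[, 3]
  d <- comp[, 4]; e <- comp[, 5]; f <- comp[, 6]
  q <- (a + b + c) / 3
  p1 <- d^2 + e^2 + f^2
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  lam <- cbind(q, q, q)
  nz <- p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(nz)) {
    ai <- (a[nz] - q[nz]) / p[nz]; bi <- (b[nz] - q[nz]) / p[nz]
    ci <- (c[nz] - q[nz]) / p[nz]
    di <- d[nz] / p[nz]; ei <- e[nz] / p[nz]; fi <- f[nz] / p[nz]
    detB <- ai * (bi * ci - fi^2) - di * (di * ci - fi * ei) +
      ei * (di * fi - bi * ei)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q[nz] + 2 * p[nz] * cos(phi)
    l3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    lam[nz, ] <- cbind(l1, 3 * q[nz] - l1 - l3, l3)
  }
  lam
}

# Project tensors with negative eigenvalues back to PSD by eigenvalue
# clipping; such voxels are rare, so they get an exact eigen() treatment.
.clip_negative_eigs <- function(comp) {
  lam <- tensor_eigenvalues(comp)
  bad <- which(lam[, 3] < 0)
  for (i in bad) {
    M <- matrix(c(comp[i, 1], comp[i, 4], comp[i, 5],
                  comp[i, 4], comp[i, 2], comp[i, 6],
                  comp[i, 5], comp[i, 6], comp[i, 3]), 3, 3)
    E <- eigen(M, symmetric = TRUE)
    M2 <- E$vectors %*% diag(pmax(E$values, 0)) %*% t(E$vectors)
    comp[i, ] <- c(M2[1, 1], M2[2, 2], M2[3, 3], M2[1, 2], M2[1, 3], M2[2, 3])
  }
  comp
}

#' Fractional anisotropy map of a tensor field
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`,
#' 0 where the tensor is zero, clipped into [0, 1]. FA is 0 for isotropic
#' diffusion and approaches 1 as diffusion collapses onto a single axis.
#'
#' @param field a `tensor_field`.
#' @return 3D array of FA values (background 0).
#' @export
fa_map <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  shape <- dim(field$D)[1:3]
  lam <- tensor_eigenvalues(matrix(field$D, ncol = 6L))
  lbar <- rowMeans(lam)
  num <- rowSums((lam - lbar)^2)
  den <- rowSums(lam^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  array(pmin(pmax(fa, 0), 1), dim = shape)
}

#' Voxelwise FA group comparison for automatic lesion ROIs
#'
#' For every voxel, a one-sided Welch (unequal-variance) two-sample t-test of
#' FA(patients) < FA(controls); the ROI is the set of voxels significant at
#' `alpha`, uncorrected. This is a voxelwise simplification of
#' skeleton-based FA group statistics: the decision rule (uncorrected
#' p < 0.005, FA decrease) is retained, the skeleton projection is not.
#' Voxels with zero variance in both groups (e.g. background) are excluded.
#'
#' @param patient_fa list of >= 2 FA arrays (patients).
#' @param control_fa list of >= 2 FA arrays (controls).
#' @param alpha one-sided significance level, default 0.005.
#' @return an `roi_mask` (possibly empty) of significant voxels.
#' @export
segment_auto_voxelwise <- function(patient_fa, control_fa, alpha = 0.005) {
  if (length(patient_fa) < 2L || length(control_fa) < 2L) {
    stop("need at least 2 FA images per group", call. = FALSE)
  }
  dims <- dim(patient_fa[[1]])
  for (x in c(patient_fa, control_fa)) check_same_grid(dim(x), dims, "FA image")
  P <- vapply(patient_fa, as.vector, numeric(prod(dims)))
  C <- vapply(control_fa, as.vector, numeric(prod(dims)))
  np <- ncol(P); nc <- ncol(C)
  mp <- rowMeans(P); mc <- rowMeans(C)
  vp <- rowSums((P - mp)^2) / (np - 1)
  vc <- rowSums((C - mc)^2) / (nc - 1)
  testable <- vp > 0 | vc > 0
  se2 <- vp / np + vc / nc
  tt <- (mc - mp) / sqrt(se2)
  df <- se2^2 / ((vp / np)^2 / (np - 1) + (vc / nc)^2 / (nc - 1))
  p <- rep(NA_real_, length(tt))
  p[testable] <- stats::pt(tt[testable], df[testable], lower.tail = FALSE)
  sig <- !is.na(p) & p < alpha
  out <- roi_mask(array(sig, dim = dims), allow_empty = TRUE)
  attr(out, "n_tested") <- sum(testable)
  out
}
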