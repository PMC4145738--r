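#' Lesion specification for the DWI phantom
#'
#' Describes a spherical lesion inserted into the symmetric phantom brain.
#' Acute ischemic lesions restrict water diffusion (mean diffusivity scaled
#' down, hence hyperintense DWI signal); chronic sequela lesions show raised
#' diffusivity (hypointense DWI signal). Both kinds typically lower the
#' anisotropy of the underlying tissue.
#'
#' @param center integer length-3, 0-based voxel coordinate of the lesion
#'   center.
#' @param radius lesion radius in mm (> 0).
#' @param kind `"acute"` or `"sequela"`.
#' @param adc_scale multiplicative factor on mean diffusivity inside the
#'   lesion; defaults 0.6 (acute) and 1.8 (sequela).
#' @param fa_scale multiplicative factor on fractional anisotropy inside the
#'   lesion; default 0.5 (both stroke stages disrupt fibre coherence).
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, kind = c("acute", "sequela"),
                        adc_scale = NULL, fa_scale = 0.5) {
  kind <- match.arg(kind)
  if (is.null(adc_scale)) adc_scale <- if (kind == "acute") 0.6 else 1.8
  if (radius <= 0) stop("lesion radius must be > 0", call. = FALSE)
  if (kind == "acute" && adc_scale >= 1) {
    stop("acute lesions must have adc_scale < 1 (restricted diffusion)",
         call. = FALSE)
  }
  if (kind == "sequela" && adc_scale <= 1) {
    stop("sequela lesions must have adc_scale > 1 (raised diffusivity)",
         call. = FALSE)
  }
  structure(list(center = as.integer(center), radius = radius, kind = kind,
                 adc_scale = adc_scale, fa_scale = fa_scale),
            class = "lesion_spec")
}

# Axially symmetric diagonal tensor with mean diffusivity `md` and fractional
# anisotropy `fa`, principal axis along y. For eigenvalues (m(1+2d), m(1-d),
# m(1-d)) the FA is 3d / sqrt(3 + 6 d^2), inverted here as d = fa/sqrt(3-2fa^2).
.axial_eigs <- function(md, fa) {
  d <- fa / sqrt(3 - 2 * fa^2)
  cbind(l1 = md * (1 + 2 * d), l2 = md * (1 - d), l3 = md * (1 - d))
}

#' Build a symmetric phantom diffusion-tensor field
#'
#' The brain is an ellipsoid centred on the grid, exactly symmetric about the
#' midplane of axis 1 (the left-right axis), filled with an axially symmetric
#' diagonal tensor whose principal axis runs along y. Anisotropy varies
#' smoothly with slice to keep the tensor-recovery tests non-trivial while
#' preserving mirror symmetry. Inside each lesion the eigenvalues are rescaled
#' so that mean diffusivity is multiplied by `adc_scale` and FA by `fa_scale`.
#'
#' @param shape integer length-3 grid shape, each >= c(16, 16, 8).
#' @param voxel_size voxel edge lengths in mm.
#' @param base_md baseline mean diffusivity in mm^2/s (default 0.8e-3,
#'   normal-appearing parenchyma).
#' @param base_fa baseline FA at the central slice (default 0.3, mild
#'   anisotropy); FA ramps +/- 0.1 linearly across slices.
#' @param lesions list of [lesion_spec()] objects; every lesion must lie
#'   strictly within one hemisphere (a lesion crossing the midplane would
#'   corrupt its own mirror reference).
#' @return a list of class `tensor_field` with elements `D` (4D array
#'   x,y,z,6 holding Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `brain_mask`
#'   (an `roi_mask`), `lesion_masks` (list of `roi_mask`), `voxel_size`.
#' @export
make_tensor_field <- function(shape, voxel_size = c(1, 1, 5),
                              base_md = 0.8e-3, base_fa = 0.3,
                              lesions = list()) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(16L, 16L, 8L))) {
    stop("grid shape must be at least 16 x 16 x 8", call. = FALSE)
  }
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  # 0-based voxel coordinates; grid centre is the midplane of each axis
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2; cz <- (nz - 1) / 2
  xs <- (0:(nx - 1) - cx) * voxel_size[1]
  ys <- (0:(ny - 1) - cy) * voxel_size[2]
  zs <- (0:(nz - 1) - cz) * voxel_size[3]
  ax <- 0.42 * nx * voxel_size[1]
  ay <- 0.45 * ny * voxel_size[2]
  az <- 0.42 * nz * voxel_size[3]
  r2 <- outer(outer((xs / ax)^2, (ys / ay)^2, "+"), (zs / az)^2, "+")
  brain <- r2 <= 1

  # slice-dependent FA ramp, symmetric in x by construction (depends on z only)
  fa_slice <- base_fa + 0.2 * ((0:(nz - 1)) / max(nz - 1, 1) - 0.5)
  fa_slice <- pmin(pmax(fa_slice, 0.05), 0.95)
  md_grid <- array(0, dim = shape)
  fa_grid <- array(0, dim = shape)
  md_grid[brain] <- base_md
  fa_vol <- aperm(array(rep(fa_slice, each = nx * ny), dim = shape), c(1, 2, 3))
  fa_grid[brain] <- fa_vol[brain]

  lesion_masks <- vector("list", length(lesions))
  if (length(lesions)) {
    mid <- (nx - 1) / 2
    coords <- arrayInd(seq_len(prod(shape)), shape) - 1L
    for (i in seq_along(lesions)) {
      ls <- lesions[[i]]
      dmm <- sweep(coords, 2, ls$center, "-")
      dmm <- sweep(dmm, 2, voxel_size, "*")
      inside <- array(rowSums(dmm^2) <= ls$radius^2, dim = shape) & brain
      if (!any(inside)) {
        stop(sprintf("lesion %d contains no brain voxels", i), call. = FALSE)
      }
      lx <- which(inside, arr.ind = TRUE)[, 1] - 1L
      if (any(lx < mid) && any(lx > mid) || any(lx == mid)) {
        stop(sprintf(
          "lesion %d touches or crosses the axis-1 midplane; it would overlap its own mirror reference",
          i), call. = FALSE)
      }
      md_grid[inside] <- md_grid[inside] * ls$adc_scale
      fa_grid[inside] <- pmin(fa_grid[inside] * ls$fa_scale, 0.95)
      lesion_masks[[i]] <- roi_mask(inside)
    }
  }

  eig <- .axial_eigs(as.vector(md_grid), as.vector(fa_grid))
  D <- array(0, dim = c(shape, 6L))
  # principal axis along y: Dyy gets l1, Dxx and Dzz the radial eigenvalues
  D[, , , 1] <- array(eig[, "l2"], dim = shape)
  D[, , , 2] <- array(eig[, "l1"], dim = shape)
  D[, , , 3] <- array(eig[, "l3"], dim = shape)
  D[!array(rep(brain, 6), dim = c(shape, 6L))] <- 0

  structure(list(D = D, brain_mask = roi_mask(brain),
                 lesion_masks = lesion_masks, voxel_size = voxel_size),
            class = "tensor_field")
}

#' Simulate the noiseless DWI signal of a tensor field
#'
#' Standard monoexponential diffusion-tensor signal model: for each volume i,
#' `S_i = s0 * exp(-b_i * g_i' D g_i)` inside the brain and 0 outside.
#'
#' @param field a `tensor_field` from [make_tensor_field()].
#' @param s0 unweighted (b = 0) signal intensity, > 0.
#' @param scheme a [gradient_scheme()].
#' @return a noiseless [dwi_image()].
#' @export
simulate_signal <- function(field, s0, scheme = default_gradient_scheme()) {
  stopifnot(inherits(field, "tensor_field"))
  if (s0 <= 0) stop("s0 must be positive", call. = FALSE)
  shape <- dim(field$D)[1:3]
  nvol <- n_volumes(scheme)
  brain <- field$brain_mask$data
  Dm <- matrix(field$D, ncol = 6L)  # voxels x 6
  out <- array(0, dim = c(shape, nvol))
  for (i in seq_len(nvol)) {
    b <- scheme$bvals[i]
    if (b == 0) {
      vol <- array(0, dim = shape); vol[brain] <- s0
    } else {
      g <- scheme$bvecs[, i]
      # g' D g from the 6 unique components
      q <- Dm[, 1] * g[1]^2 + Dm[, 2] * g[2]^2 + Dm[, 3] * g[3]^2 +
        2 * (Dm[, 4] * g[1] * g[2] + Dm[, 5] * g[1] * g[3] +
               Dm[, 6] * g[2] * g[3])
      vol <- array(s0 * exp(-b * q), dim = shape)
      vol[!brain] <- 0
    }
    out[, , , i] <- vol
  }
  dwi_image(out, field$voxel_size, scheme)
}

#' Add Rician noise to a DWI image
#'
#' Magnitude-MRI noise: each intensity S is replaced by
#' `sqrt((S + n1)^2 + n2^2)` with n1, n2 independent zero-mean Gaussians of
#' standard deviation `sigma`. Deterministic given `seed`.
#'
#' @param img a `dwi_image`.
#' @param sigma Gaussian channel noise standard deviation, >= 0 (same units as
#'   the image intensities).
#' @param seed integer seed.
#' @return a `dwi_image` with noise applied.
#' @export
add_rician_noise <- function(img, sigma, seed) {
  stopifnot(inherits(img, "dwi_image"))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  n <- length(img$data)
  noisy <- with_preserved_seed(as.integer(seed), {
    n1 <- stats::rnorm(n, sd = sigma)
    n2 <- stats::rnorm(n, sd = sigma)
    sqrt((as.vector(img$data) + n1)^2 + n2^2)
  })
  dwi_image(array(noisy, dim = dim(img$data)), img$voxel_size, img$scheme)
}

#' Default phantom cohort parameters
#'
#' The settings that define the package's synthetic study conditions: a
#' 48 x 48 x 20 grid at 1 x 1 x 5 mm (the study's in-plane resolution and
#' slice thickness at desk scale), baseline mean diffusivity 0.8e-3 mm^2/s
#' with mild anisotropy, acute lesions at 0.6x ADC, sequela at 1.8x, spherical
#' lesions of 6 mm radius, s0 = 1000 with Rician sigma = 2% of s0.
#'
#' @return a named list of parameters accepted by [make_cohort()].
#' @export
default_phantom_params <- function() {
  list(shape = c(48L, 48L, 20L), voxel_size = c(1, 1, 5),
       base_md = 0.8e-3, base_fa = 0.3, s0 = 1000,
       noise_sigma = 20, lesion_radius = 6,
       acute_adc_scale = 0.6, sequela_adc_scale = 1.8, fa_scale = 0.5,
       smooth_fwhm = 3)
}

# Deterministic per-subject sub-seeds below 2^31 from one master seed.
.subject_seeds <- function(master_seed, n) {
  with_preserved_seed(as.integer(master_seed),
                      sample.int(.Machine$integer.max - 1L, n))
}

# Jittered lesion centre in the left hemisphere (axis-1 index < midplane),
# clear of both the midplane and the brain edge.
.lesion_center <- function(shape, voxel_size, radius) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  rx <- ceiling(radius / voxel_size[1]); rz <- ceiling(radius / voxel_size[3])
  x_hi <- floor((nx - 1) / 2) - rx  # keep the whole sphere left of midplane
  if (x_hi < rx) {
    stop(sprintf("lesion radius %.3g mm does not fit one hemisphere of a %d-wide grid",
                 radius, nx), call. = FALSE)
  }
  x <- round(nx * 0.28) + sample(-2:2, 1)
  x <- max(rx, min(x, x_hi))
  y <- round(ny / 2) + sample(-4:4, 1)
  z <- round(nz / 2) + sample(-1:1, 1)
  z <- max(rz, min(z, nz - 1 - rz))
  c(x, y, z)
}

#' Generate a synthetic DWI cohort
#'
#' Builds `n_normal + n_acute + n_sequela` subjects with deterministic
#' per-subject seeds derived from `master_seed`. Normals (class 1) have no
#' lesion; acute subjects (class 2) carry a reduced-ADC lesion (hyperintense
#' on DWI); sequela subjects (class 3) a raised-ADC lesion (hypointense).
#' Lesion centers are jittered between subjects within the left hemisphere.
#'
#' @param n_normal,n_acute,n_sequela subject counts per class, >= 0.
#' @param params parameter list, see [default_phantom_params()].
#' @param master_seed integer master seed.
#' @return list of subjects, each a list with elements `id`, `class`
#'   (1/2/3), `seed`, `dwi` (a `dwi_image`), `truth_lesion` (`roi_mask`,
#'   empty for normals), `brain_mask` (`roi_mask`), and `lesion` (the
#'   `lesion_spec` or NULL).
#' @export
make_cohort <- function(n_normal = 8, n_acute = 8, n_sequela = 3,
                        params = default_phantom_params(), master_seed = 42) {
  stopifnot(n_normal >= 0, n_acute >= 0, n_sequela >= 0)
  n <- n_normal + n_acute + n_sequela
  if (n == 0) stop("cohort must contain at least one subject", call. = FALSE)
  classes <- rep(1:3, times = c(n_normal, n_acute, n_sequela))
  seeds <- .subject_seeds(master_seed, n)
  scheme <- default_gradient_scheme()
  lapply(seq_len(n), function(i) {
    cls <- classes[i]
    seed <- seeds[i]
    lesion <- NULL
    if (cls > 1L) {
      lesion <- with_preserved_seed(seed, {
        ctr <- .lesion_center(params$shape, params$voxel_size,
                              params$lesion_radius)
        if (cls == 2L) {
          lesion_spec(ctr, params$lesion_radius, "acute",
                      adc_scale = params$acute_adc_scale,
                      fa_scale = params$fa_scale)
        } else {
          lesion_spec(ctr, params$lesion_radius, "sequela",
                      adc_scale = params$sequela_adc_scale,
                      fa_scale = params$fa_scale)
        }
      })
    }
    field <- make_tensor_field(params$shape, params$voxel_size,
                               base_md = params$base_md,
                               base_fa = params$base_fa,
                               lesions = if (is.null(lesion)) list()
                                         else list(lesion))
    dwi <- simulate_signal(field, s0 = params$s0, scheme = scheme)
    if (params$noise_sigma > 0) {
      dwi <- add_rician_noise(dwi, params$noise_sigma, seed = seed + 1L)
    }
    truth <- if (is.null(lesion)) {
      roi_mask(array(FALSE, dim = params$shape), allow_empty = TRUE)
    } else field$lesion_masks[[1]]
    list(id = i, class = cls, seed = seed, dwi = dwi, truth_lesion = truth,
         brain_mask = field$brain_mask, lesion = lesion)
  })
}
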