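#' 4D diffusion-weighted image
#'
#' Couples a 4D non-negative intensity array (x, y, z, volume) with its voxel
#' geometry and gradient scheme. The first array axis is the left-right axis;
#' the midsagittal plane is the midplane of that axis, which is what makes the
#' contralateral mirror operations in this package a pure index reversal
#' (inputs are assumed co-registered to a symmetric template space).
#'
#' @param data 4D numeric array, all values finite and >= 0.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param scheme a [gradient_scheme()]; its length must equal `dim(data)[4]`.
#' @return an object of class `dwi_image`.
#' @export
dwi_image <- function(data, voxel_size, scheme) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("`data` must be a 4D array (x, y, z, volume)", call. = FALSE)
  }
  if (any(dim(data) == 0L)) stop("image has an empty dimension", call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive lengths in mm", call. = FALSE)
  }
  if (!inherits(scheme, "gradient_scheme")) {
    stop("`scheme` must be a gradient_scheme", call. = FALSE)
  }
  if (dim(data)[4] != n_volumes(scheme)) {
    stop(sprintf("image has %d volumes but scheme has %d entries",
                 dim(data)[4], n_volumes(scheme)), call. = FALSE)
  }
  structure(list(data = data, voxel_size = voxel_size, scheme = scheme),
            class = "dwi_image")
}

#' Spatial grid shape of a DWI image
#' @param img a `dwi_image`.
#' @return integer length-3 spatial dimensions.
#' @export
grid_shape <- function(img) dim(img$data)[1:3]

#' @export
print.dwi_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_image %dx%dx%d, %d volumes, voxels %.3gx%.3gx%.3g mm>\n",
              d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A 3D logical mask on the same spatial grid as a `dwi_image`. Non-logical
#' input is binarized (nonzero is inside).
#'
#' @param data 3D array, logical or numeric.
#' @param allow_empty if `FALSE` (default for target ROIs) an all-FALSE mask is
#'   an error; empty masks are legitimate for "no lesion found" outcomes and
#'   for normal subjects' truth masks, which pass `allow_empty = TRUE`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(data, allow_empty = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  m <- array(as.logical(data != 0), dim = dim(data))
  if (!allow_empty && !any(m)) {
    stop("ROI mask is empty (no voxels inside)", call. = FALSE)
  }
  structure(list(data = m), class = "roi_mask")
}

#' Number of voxels inside a mask
#' @param mask an `roi_mask`.
#' @return integer voxel count.
#' @export
mask_size <- function(mask) sum(mask$data)

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<roi_mask %dx%dx%d, %d voxels inside>\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

# Stop unless mask and image (or two masks) share a spatial grid.
check_same_grid <- function(shape_a, shape_b, what = "mask") {
  if (!identical(as.integer(shape_a), as.integer(shape_b))) {
    stop(sprintf("%s grid (%s) does not match expected grid (%s)",
                 what, paste(shape_a, collapse = "x"),
                 paste(shape_b, collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}
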