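#' Read a DWI image with its FSL-style gradient table
#'
#' Reads a NIfTI volume together with `.bval`/`.bvec` text files (FSL dialect:
#' bvals on one whitespace-separated line, bvecs as 3 rows of n columns) and
#' returns a validated [dwi_image()].
#'
#' @param image_path path to a `.nii` / `.nii.gz` 4D volume.
#' @param bval_path,bvec_path paths to the gradient table text files.
#' @param order_tag ordering tag recorded on the scheme.
#' @return a `dwi_image`.
#' @export
read_dwi <- function(image_path, bval_path, bvec_path,
                     order_tag = "from-file") {
  for (p in c(image_path, bval_path, bvec_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  nii <- RNifti::readNifti(image_path)
  arr <- array(as.vector(nii), dim = dim(nii))  # plain array, no header attrs
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  dimnames(bvecs) <- NULL
  if (length(bvals) != dim(arr)[4] || ncol(bvecs) != dim(arr)[4]) {
    stop(sprintf(
      "gradient table does not match image: %d volumes vs %d b-values / %d directions",
      dim(arr)[4], length(bvals), ncol(bvecs)), call. = FALSE)
  }
  vs <- RNifti::pixdim(nii)[1:3]
  dwi_image(arr, vs, gradient_scheme(bvals, bvecs, order_tag = order_tag))
}

#' Write a DWI image and its gradient table
#'
#' @param img a `dwi_image`.
#' @param image_path destination `.nii` / `.nii.gz` path.
#' @param bval_path,bvec_path destination gradient table paths.
#' @return invisibly, a named character vector of the three paths written.
#' @export
write_dwi <- function(img, image_path, bval_path, bvec_path) {
  stopifnot(inherits(img, "dwi_image"))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- c(img$voxel_size, 1)
  RNifti::writeNifti(nii, image_path)
  writeLines(paste(format(img$scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  utils::write.table(format(img$scheme$bvecs, trim = TRUE, digits = 17),
                     bvec_path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(c(image = image_path, bval = bval_path, bvec = bvec_path))
}

#' Read a binary ROI mask from NIfTI
#'
#' Nonzero voxels are inside. The mask must live on the expected spatial grid;
#' affine resampling between grids is out of scope.
#'
#' @param path NIfTI path.
#' @param expected_shape integer length-3 spatial shape the mask must match.
#' @param allow_empty passed to [roi_mask()].
#' @return an `roi_mask`.
#' @export
read_mask <- function(path, expected_shape, allow_empty = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  nii <- RNifti::readNifti(path)
  arr <- array(as.vector(nii), dim = dim(nii))
  if (length(dim(arr)) != 3L) stop("mask must be a 3D volume", call. = FALSE)
  check_same_grid(dim(arr), expected_shape, what = "mask")
  roi_mask(arr, allow_empty = allow_empty)
}

#' Write a binary ROI mask to NIfTI
#' @param mask an `roi_mask`.
#' @param path destination path.
#' @param voxel_size voxel edge lengths in mm recorded in the header.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(mask, "roi_mask"))
  nii <- RNifti::asNifti(array(as.numeric(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(nii) <- voxel_size
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' The packaged clinical clustering table
#'
#' Returns the package's transcription of the study's per-subject table: 19
#' subjects, the clinical reference class (1 = normal control, 2 = acute
#' stroke, 3 = stroke sequela) and the six clustering label columns produced
#' by the three ROI methods crossed with the two distance metrics (ME/MC =
#' manual, SE/SC = semiautomatic, AE/AC = automatic; E = Euclidean,
#' C = cosine). This table is the in-study ground truth against which the
#' evaluation module's F-scores and accuracies are computed.
#'
#' @return a data.frame with columns `subject`, `clinical`, `ME`, `MC`, `SE`,
#'   `SC`, `AE`, `AC`; exactly 19 rows; clinical class counts 8/8/3.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "dwifinger",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, colClasses = "integer")
  stopifnot(
    nrow(tab) == 19L,
    identical(names(tab), c("subject", "clinical", "ME", "MC", "SE", "SC",
                            "AE", "AC")),
    identical(tab$subject, 1:19),
    identical(as.integer(table(factor(tab$clinical, levels = 1:3))),
              c(8L, 8L, 3L)),
    all(as.matrix(tab[, -1]) %in% 1:3))
  tab
}
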