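#' Build a subject's neural fingerprint
#'
#' The fingerprint is the 20-element feature vector at the core of the
#' method: for each diffusion-weighted volume i, element i is the ratio of
#' the mean intensity inside the target ROI to the mean intensity inside the
#' contralateral mirror ROI. The within-subject mirror reference cancels
#' global intensity gain, so fingerprints are comparable across subjects and
#' scanners; normal tissue gives ratios near 1, restricted diffusion (acute
#' ischemia) ratios above 1, elevated diffusivity (sequela) below 1. The
#' b = 0 volume is excluded: the vector is indexed by the 20 diffusion
#' gradients in scheme order.
#'
#' @param img a `dwi_image`.
#' @param target target `roi_mask` (nonempty).
#' @param mirror mirror `roi_mask`; defaults to `mirror_mask(target)`.
#' @param subject_id optional identifier stored on the result.
#' @param roi_method one of `"manual"`, `"semiauto"`, `"auto"` (metadata).
#' @return an object of class `fingerprint`: numeric vector of positive
#'   ratios (length = number of b > 0 volumes) with attributes `subject_id`
#'   and `roi_method`.
#' @export
build_fingerprint <- function(img, target, mirror = NULL,
                              subject_id = NA_integer_,
                              roi_method = c("manual", "semiauto", "auto")) {
  roi_method <- match.arg(roi_method)
  stopifnot(inherits(img, "dwi_image"), inherits(target, "roi_mask"))
  check_same_grid(dim(target$data), grid_shape(img), "target mask")
  if (!any(target$data)) stop("target ROI is empty", call. = FALSE)
  if (is.null(mirror)) mirror <- mirror_mask(target)
  stopifnot(inherits(mirror, "roi_mask"))
  check_same_grid(dim(mirror$data), grid_shape(img), "mirror mask")
  if (!any(mirror$data)) stop("mirror ROI is empty", call. = FALSE)

  dw <- which(img$scheme$bvals > 0)
  m <- matrix(img$data, ncol = dim(img$data)[4])
  tsel <- which(target$data); msel <- which(mirror$data)
  num <- colMeans(m[tsel, dw, drop = FALSE])
  den <- colMeans(m[msel, dw, drop = FALSE])
  if (any(den <= 0)) {
    stop("mirror ROI has zero mean intensity at some gradient: degenerate reference",
         call. = FALSE)
  }
  structure(num / den, class = "fingerprint",
            subject_id = subject_id, roi_method = roi_method)
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint subject %s (%s): %d ratios, range %.3f-%.3f>\n",
              attr(x, "subject_id"), attr(x, "roi_method"), length(x),
              min(x), max(x)))
  invisible(x)
}

#' Assemble a cohort fingerprint table
#'
#' Binds per-subject fingerprints into the tabular interchange form used
#' between the imaging and clustering halves of the pipeline.
#'
#' @param fingerprints list of `fingerprint` objects of equal length.
#' @param classes optional integer clinical classes (1/2/3), recycled in.
#' @return a data.frame with columns `subject`, `class`, `g01..gNN`,
#'   `roi_method`.
#' @export
fingerprint_table <- function(fingerprints, classes = NA_integer_) {
  stopifnot(length(fingerprints) >= 1L)
  len <- unique(vapply(fingerprints, length, integer(1)))
  if (length(len) != 1L) {
    stop("fingerprints have unequal lengths", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(fingerprints, as.numeric))
  colnames(mat) <- sprintf("g%02d", seq_len(len))
  data.frame(
    subject = vapply(fingerprints, function(f)
      as.integer(attr(f, "subject_id")), integer(1)),
    class = rep_len(as.integer(classes), length(fingerprints)),
    mat,
    roi_method = vapply(fingerprints, function(f)
      as.character(attr(f, "roi_method")), character(1)))
}

#' Extract the fingerprint matrix from a fingerprint table
#' @param tab a data.frame from [fingerprint_table()] (or read back from CSV).
#' @return numeric matrix, subjects x gradients.
#' @export
fingerprint_matrix <- function(tab) {
  as.matrix(tab[, grep("^g[0-9]+$", names(tab)), drop = FALSE])
}
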