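#' Mirror a mask across the midsagittal plane
#'
#' Reverses the mask along axis 1 about the grid midplane: voxel (x, y, z)
#' maps to (Nx - 1 - x, y, z) in 0-based coordinates. In template space this
#' produces the contralateral ("mirror") ROI used as the per-subject intensity
#' reference.
#'
#' @param mask an `roi_mask`.
#' @return the mirrored `roi_mask` (same voxel count; involution).
#' @export
mirror_mask <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  nx <- dim(mask$data)[1]
  roi_mask(mask$data[nx:1, , , drop = FALSE], allow_empty = TRUE)
}

#' Intersection of two raters' masks
#'
#' Voxelwise AND of two manual delineations on the same grid; the consensus
#' lesion ROI. An empty intersection signals rater disagreement and is an
#' error rather than a silent empty ROI.
#'
#' @param mask_a,mask_b `roi_mask` objects on the same grid.
#' @return the intersection `roi_mask` (nonempty).
#' @export
intersect_rater_masks <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "roi_mask"), inherits(mask_b, "roi_mask"))
  check_same_grid(dim(mask_a$data), dim(mask_b$data))
  inter <- mask_a$data & mask_b$data
  if (!any(inter)) {
    stop("rater masks have empty intersection: no consensus ROI", call. = FALSE)
  }
  roi_mask(inter)
}

#' One hemisphere of a brain mask
#'
#' Brain voxels strictly on one side of the axis-1 midplane; for odd grid
#' widths the midplane column belongs to neither hemisphere. Used as the
#' target ROI of normal subjects, for whom there is no lesion to delineate.
#'
#' @param brain_mask an `roi_mask`.
#' @param side `"left"` (axis-1 index below midplane) or `"right"`.
#' @return an `roi_mask`.
#' @export
hemisphere_mask <- function(brain_mask, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(brain_mask, "roi_mask"))
  nx <- dim(brain_mask$data)[1]
  mid <- (nx - 1) / 2  # 0-based midplane
  x0 <- seq_len(nx) - 1L
  keep <- if (side == "left") x0 < mid else x0 > mid
  m <- brain_mask$data
  m[!keep, , ] <- FALSE
  if (!any(m)) {
    stop(sprintf("brain mask empty on the %s side", side), call. = FALSE)
  }
  roi_mask(m)
}

#' Voxelwise left-right difference map
#'
#' For every brain voxel v, `value(v) - value(mirror(v))`: the asymmetry
#' signal on which the semiautomatic segmentation operates. Hyperintense
#' (acute) lesions produce positive values at the lesion and, by
#' antisymmetry, negative values at its mirror site; background is 0.
#'
#' @param mean_image 3D array, typically from [mean_over_gradients()].
#' @param brain_mask an `roi_mask` on the same grid.
#' @return a 3D signed array, zero outside the brain.
#' @export
difference_map <- function(mean_image, brain_mask) {
  stopifnot(is.array(mean_image), length(dim(mean_image)) == 3L,
            inherits(brain_mask, "roi_mask"))
  check_same_grid(dim(mean_image), dim(brain_mask$data), "mean image")
  nx <- dim(mean_image)[1]
  d <- mean_image - mean_image[nx:1, , , drop = FALSE]
  d[!brain_mask$data] <- 0
  d
}

#' Derive the two lesion-identification thresholds
#'
#' Implements the histogram-threshold calibration of the semiautomatic
#' method: one reference subject per class (normal, acute, sequela), each
#' with a drawn target ROI, contributes the difference-map values inside its
#' ROI. Each class sample's density is estimated by Gaussian kernel density
#' estimation with Silverman's bandwidth, and the thresholds are the density
#' crossings between neighbouring classes: `t1` between sequela (left tail)
#' and normal, `t2` between normal and acute (right tail). If two densities
#' never cross between their class means, the midpoint of the means is used
#' with a warning.
#'
#' @param reference list of three elements named `normal`, `acute`,
#'   `sequela`; each a list with `diff_map` (3D array from
#'   [difference_map()]) and `target` (an `roi_mask`).
#' @return a list of class `threshold_pair` with numeric `t1 < t2` and the
#'   per-class sample means.
#' @export
derive_thresholds <- function(reference) {
  need <- c("normal", "acute", "sequela")
  if (!all(need %in% names(reference))) {
    stop("reference must contain subjects named 'normal', 'acute', 'sequela'",
         call. = FALSE)
  }
  vals <- lapply(reference[need], function(s) {
    stopifnot(inherits(s$target, "roi_mask"))
    v <- s$diff_map[s$target$data]
    if (length(v) < 2L) stop("reference ROI too small", call. = FALSE)
    v
  })
  mu <- vapply(vals, mean, numeric(1))
  t1 <- .density_crossing(vals$sequela, vals$normal,
                          mu["sequela"], mu["normal"])
  t2 <- .density_crossing(vals$normal, vals$acute,
                          mu["normal"], mu["acute"])
  if (t1 >= t2) {
    warning("degenerate threshold ordering; falling back to class-mean midpoints")
    t1 <- (mu[["sequela"]] + mu[["normal"]]) / 2
    t2 <- (mu[["normal"]] + mu[["acute"]]) / 2
  }
  structure(list(t1 = t1, t2 = t2, class_means = mu),
            class = "threshold_pair")
}

# Crossing point of two kernel density estimates, restricted to the interval
# between the class means; closest-to-midpoint crossing wins when several
# exist. Falls back (with a warning) to the midpoint when the densities do
# not cross between the means.
.density_crossing <- function(x_lo, x_hi, mu_lo, mu_hi) {
  if (mu_lo > mu_hi) {  # keep the search interval ordered
    tmp <- x_lo; x_lo <- x_hi; x_hi <- tmp
    tmp <- mu_lo; mu_lo <- mu_hi; mu_hi <- tmp
  }
  mid <- (mu_lo + mu_hi) / 2
  if (mu_hi - mu_lo < .Machine$double.eps^0.5) {
    warning("reference class means coincide; threshold set to their midpoint")
    return(mid)
  }
  grid <- seq(mu_lo, mu_hi, length.out = 512L)
  d_lo <- .kde_at(x_lo, grid)
  d_hi <- .kde_at(x_hi, grid)
  s <- sign(d_lo - d_hi)
  flips <- which(s[-1] * s[-length(s)] < 0)
  if (!length(flips)) {
    warning("densities do not cross between class means; using midpoint")
    return(mid)
  }
  cand <- (grid[flips] + grid[flips + 1L]) / 2
  cand[which.min(abs(cand - mid))]
}

# Gaussian KDE with Silverman's bandwidth evaluated at arbitrary points.
.kde_at <- function(x, at) {
  bw <- stats::bw.nrd0(x)
  if (bw <= 0) bw <- .Machine$double.eps^0.5
  vapply(at, function(p) mean(stats::dnorm(p, mean = x, sd = bw)), numeric(1))
}

#' Semiautomatic lesion segmentation by mirror-difference thresholding
#'
#' Applies calibrated thresholds to a subject's difference map: voxels with
#' difference above `t2` are acute-like candidates, voxels below `t1`
#' sequela-like. The candidate set with the larger summed absolute
#' difference wins (ties go to acute-like), is restricted to its dominant
#' hemisphere, and the largest 26-connected component is returned as the
#' lesion ROI. An empty candidate set is a legitimate "no-lesion" outcome,
#' not an error.
#'
#' @param mean_image 3D mean DWI array (see [mean_over_gradients()]).
#' @param brain_mask an `roi_mask`.
#' @param thresholds a `threshold_pair` from [derive_thresholds()].
#' @return a list with `roi` (an `roi_mask`, possibly empty) and
#'   `lesion_kind` (`"acute"`, `"sequela"`, or `"no-lesion"`).
#' @export
segment_semiauto <- function(mean_image, brain_mask, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  d <- difference_map(mean_image, brain_mask)
  cand_acute <- d > thresholds$t2 & brain_mask$data
  cand_seq <- d < thresholds$t1 & brain_mask$data
  s_acute <- sum(abs(d[cand_acute]))
  s_seq <- sum(abs(d[cand_seq]))
  if (s_acute == 0 && s_seq == 0) {
    return(list(roi = roi_mask(array(FALSE, dim(d)), allow_empty = TRUE),
                lesion_kind = "no-lesion"))
  }
  if (s_acute >= s_seq) {
    cand <- cand_acute; kind <- "acute"
  } else {
    cand <- cand_seq; kind <- "sequela"
  }
  # keep the hemisphere carrying more candidate |difference| (left on ties),
  # so the returned ROI can never straddle the midline
  nx <- dim(d)[1]
  x0 <- seq_len(nx) - 1L
  mid <- (nx - 1) / 2
  left <- cand; left[x0 >= mid, , ] <- FALSE
  right <- cand; right[x0 <= mid, , ] <- FALSE
  cand <- if (sum(abs(d[left])) >= sum(abs(d[right]))) left else right
  if (!any(cand)) {
    return(list(roi = roi_mask(array(FALSE, dim(d)), allow_empty = TRUE),
                lesion_kind = "no-lesion"))
  }
  comp <- largest_component(cand, weights = abs(d))
  list(roi = roi_mask(comp, allow_empty = TRUE), lesion_kind = kind)
}

#' Largest 26-connected component of a binary 3D array
#'
#' Components are labelled under 26-neighbourhood connectivity; the component
#' with the most voxels is returned, ties broken by the larger summed weight
#' (then by lowest linear index, for determinism).
#'
#' @param mask logical 3D array.
#' @param weights optional nonnegative 3D array used for tie-breaking.
#' @return logical 3D array containing only the winning component.
#' @export
largest_component <- function(mask, weights = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(array(FALSE, dims))
  lab <- array(0L, dims)
  nbh <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbh <- nbh[rowSums(abs(nbh)) > 0, , drop = FALSE]
  coords <- arrayInd(idx, dims)
  inside <- array(FALSE, dims); inside[idx] <- TRUE
  current <- 0L
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    current <- current + 1L
    queue <- matrix(coords[s, ], ncol = 3)
    lab[idx[s]] <- current
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(nbh, 2, as.numeric(p), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] * (nb[, 3] - 1L)
      new <- lin[inside[lin] & lab[lin] == 0L]
      if (length(new)) {
        lab[new] <- current
        queue <- rbind(queue, arrayInd(new, dims))
      }
    }
  }
  sizes <- tabulate(lab[idx], nbins = current)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L && !is.null(weights)) {
    wsum <- vapply(best, function(l) sum(weights[lab == l]), numeric(1))
    best <- best[wsum == max(wsum)]
  }
  best <- best[1L]
  out <- array(FALSE, dims)
  out[lab == best] <- TRUE
  out
}
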