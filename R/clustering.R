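#' Euclidean distance between two fingerprints
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)),
         call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

#' Cosine distance between two fingerprints
#'
#' `1 - x.y / (||x|| ||y||)`: zero for parallel vectors, 1 for orthogonal,
#' up to 2 for antiparallel. Invariant to positive rescaling of either
#' argument, which is why the cosine metric ignores the overall magnitude of
#' a fingerprint and clusters on its shape across gradients only.
#'
#' @param x,y numeric nonzero vectors of equal length.
#' @return scalar in [0, 2].
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)),
         call. = FALSE)
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("cosine distance undefined for a zero vector", call. = FALSE)
  }
  1 - sum(x * y) / (nx * ny)
}

#' K-means clustering of fingerprints under Euclidean or cosine distance
#'
#' Lloyd's algorithm: assign every subject to the nearest centroid under the
#' chosen metric, recompute centroids, stop when assignments no longer
#' change. Under the Euclidean metric the centroid is the arithmetic mean
#' and the objective is the within-cluster sum of squares (WCSS); under the
#' cosine metric the centroid is the renormalized mean of unit-normalized
#' members (spherical update) and the objective is the summed cosine
#' distance to the centroid. Each run starts from greedy farthest-point
#' seeds; `n_restarts` additional random initializations are tried and the
#' best objective wins. Ties in nearest-centroid assignment break to the
#' lowest cluster index, empty clusters are re-seeded with the point
#' farthest from its centroid, and everything is deterministic given `seed`.
#'
#' @param x numeric matrix, subjects in rows (e.g. [fingerprint_matrix()]).
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param seed integer seed for the restarts.
#' @param n_restarts random restarts beyond the farthest-point run.
#' @return an object of class `cluster_result`: list with `labels` (integers
#'   in 1..k), `centroids` (k x p), `objective`, `metric`, `seed`, `n_iter`.
#' @export
fp_kmeans <- function(x, k = 3, metric = c("euclidean", "cosine"),
                      seed = 1, n_restarts = 100) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) {
    stop(sprintf("k = %d must be between 1 and the number of subjects (%d)",
                 k, n), call. = FALSE)
  }
  if (metric == "cosine" && any(rowSums(x^2) == 0)) {
    stop("cosine metric undefined for zero fingerprints", call. = FALSE)
  }
  starts <- with_preserved_seed(as.integer(seed), {
    c(list(.farthest_point_seeds(x, k, metric)),
      lapply(seq_len(n_restarts), function(i) sample.int(n, k)))
  })
  best <- NULL
  for (st in starts) {
    run <- .lloyd(x, x[st, , drop = FALSE], metric)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  structure(list(labels = best$labels, centroids = best$centroids,
                 objective = best$objective, metric = metric,
                 seed = as.integer(seed), n_iter = best$n_iter),
            class = "cluster_result")
}

# Greedy farthest-point initialization: start from the point with the
# largest norm (deterministic), then repeatedly add the point farthest from
# the chosen set.
.farthest_point_seeds <- function(x, k, metric) {
  n <- nrow(x)
  dfun <- if (metric == "euclidean") euclidean_distance else cosine_distance
  chosen <- which.max(rowSums(x^2))
  while (length(chosen) < k) {
    dmin <- vapply(seq_len(n), function(i) {
      min(vapply(chosen, function(j) dfun(x[i, ], x[j, ]), numeric(1)))
    }, numeric(1))
    dmin[chosen] <- -Inf
    chosen <- c(chosen, which.max(dmin))
  }
  chosen
}

# All pairwise distances from rows of x to rows of centers.
.dist_to_centers <- function(x, centers, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
    sqrt(pmax(d2, 0))
  } else {
    xn <- x / sqrt(rowSums(x^2))
    cn <- centers / sqrt(rowSums(centers^2))
    1 - tcrossprod(xn, cn)
  }
}

.centroid_update <- function(x, labels, k, metric) {
  p <- ncol(x)
  cent <- matrix(NA_real_, k, p)
  for (j in seq_len(k)) {
    member <- x[labels == j, , drop = FALSE]
    if (metric == "euclidean") {
      cent[j, ] <- colMeans(member)
    } else {
      u <- member / sqrt(rowSums(member^2))
      m <- colMeans(u)
      nm <- sqrt(sum(m^2))
      cent[j, ] <- if (nm > 0) m / nm else u[1, ]
    }
  }
  cent
}

.lloyd <- function(x, centers, metric, max_iter = 100L) {
  n <- nrow(x); k <- nrow(centers)
  labels <- integer(n)
  prev_obj <- Inf
  for (iter in seq_len(max_iter)) {
    d <- .dist_to_centers(x, centers, metric)
    new_labels <- max.col(-d, ties.method = "first")
    # re-seed empty clusters with the point farthest from its own centroid
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(d[cbind(seq_len(n), new_labels)] *
                           (tabulate(new_labels, k)[new_labels] > 1))
        new_labels[far] <- j
      }
    }
    obj <- .kmeans_objective(x, new_labels, metric,
                             .centroid_update(x, new_labels, k, metric))
    stopifnot(obj <= prev_obj + 1e-8)  # Lloyd never increases the objective
    if (identical(new_labels, labels)) {
      labels <- new_labels
      break
    }
    labels <- new_labels
    centers <- .centroid_update(x, labels, k, metric)
    prev_obj <- obj
  }
  list(labels = labels, centroids = centers,
       objective = .kmeans_objective(x, labels, metric, centers),
       n_iter = iter)
}

# Clustering objective: WCSS for euclidean, summed cosine distance to the
# spherical centroid for cosine.
.kmeans_objective <- function(x, labels, metric, centers = NULL) {
  k <- max(labels)
  if (is.null(centers)) centers <- .centroid_update(x, labels, k, metric)
  d <- .dist_to_centers(x, centers, metric)
  per_point <- d[cbind(seq_len(nrow(x)), labels)]
  if (metric == "euclidean") sum(per_point^2) else sum(per_point)
}

#' Align cluster labels to a reference labelling
#'
#' Cluster labels are arbitrary; this finds the one-to-one relabelling that
#' maximizes the agreement count with the reference, by exhaustive
#' enumeration over injective label mappings (cheap for k <= 4). Cluster
#' labels with no counterpart keep an unused reference label.
#'
#' @param labels integer cluster labels, or a `cluster_result`.
#' @param reference integer reference labels of the same length.
#' @return list with `labels` (relabelled), `mapping` (named vector old ->
#'   new) and `agreement` (matching count under the best mapping).
#' @export
align_labels <- function(labels, reference) {
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  if (length(labels) != length(reference)) {
    stop("labels and reference must have equal length", call. = FALSE)
  }
  from <- sort(unique(labels))
  to <- sort(unique(c(reference, labels)))
  if (length(to) > 7L) stop("too many distinct labels for exhaustive alignment",
                            call. = FALSE)
  perms <- .permutations(to)
  best <- NULL; best_agree <- -1L
  for (p in perms) {
    map <- p[seq_along(from)]
    relab <- map[match(labels, from)]
    agree <- sum(relab == reference)
    if (agree > best_agree) {
      best_agree <- agree
      best <- list(map = map, relab = relab)
    }
  }
  list(labels = best$relab,
       mapping = stats::setNames(best$map, from),
       agreement = best_agree)
}

# All permutations of a vector (small k only).
.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d points, k = %d, %s, objective %.5g, %d iterations>\n",
              length(x$labels), nrow(x$centroids), x$metric, x$objective,
              x$n_iter))
  invisible(x)
}
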