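#' Class-weighted clustering F-score
#'
#' Scores a clustering against reference classes. For every reference class
#' P_j the best-matching cluster C_i is found under the harmonic mean of
#' precision `|Pj n Ci| / |Ci|` ("correct results over all returned
#' results") and recall `|Pj n Ci| / |Pj|`; the score is the class-size
#' weighted sum of those best matches:
#' `F = sum_j (|Pj| / n) * max_i 2 P R / (P + R)`. F is 1 exactly when the
#' clustering reproduces the reference partition (up to relabelling) and
#' tends to 0 as the partitions decouple. Pairs with empty intersection
#' contribute 0 to the max.
#'
#' @param reference vector of reference class labels.
#' @param clusters vector of cluster labels on the same subjects.
#' @return scalar in [0, 1].
#' @export
clustering_f_score <- function(reference, clusters) {
  if (length(reference) != length(clusters)) {
    stop("reference and clusters must have equal length", call. = FALSE)
  }
  if (!length(reference)) stop("empty partition", call. = FALSE)
  n <- length(reference)
  total <- 0
  for (j in unique(reference)) {
    pj <- reference == j
    best <- 0
    for (i in unique(clusters)) {
      ci <- clusters == i
      inter <- sum(pj & ci)
      if (inter == 0) next
      prec <- inter / sum(ci)
      rec <- inter / sum(pj)
      best <- max(best, 2 * prec * rec / (prec + rec))
    }
    total <- total + sum(pj) / n * best
  }
  total
}

#' Round half away from zero
#'
#' Base R rounds half to even; the printed clinical metrics use conventional
#' half-up rounding (68.42 -> 68, 89.47 -> 89, 63.16 -> 63), so the package
#' states and uses that rule explicitly.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Direct-match clustering accuracy
#'
#' Fraction of subjects whose cluster label equals the reference class. With
#' `align = TRUE` the labels are first optimally relabelled via
#' [align_labels()] (appropriate for de-novo clusterings, whose labels are
#' arbitrary); with `align = FALSE` labels are compared as given
#' (appropriate for label columns already matched to the reference).
#'
#' @param reference,labels equal-length label vectors.
#' @param align relabel before comparing.
#' @return list with `fraction`, `percent` (half-up integer), `n_match`, `n`.
#' @export
accuracy <- function(reference, labels, align = FALSE) {
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  if (length(reference) != length(labels)) {
    stop("reference and labels must have equal length", call. = FALSE)
  }
  if (align) labels <- align_labels(labels, reference)$labels
  n <- length(reference)
  n_match <- sum(reference == labels)
  list(fraction = n_match / n,
       percent = round_half_up(100 * n_match / n),
       n_match = n_match, n = n)
}

#' Wald confidence interval for a proportion, in percent
#'
#' Normal-approximation interval `p +/- z sqrt(p (1 - p) / n)` with
#' z = 1.96, clipped to [0, 100] and rounded half-up to integer percent —
#' the convention behind the reported accuracy intervals (13/19 -> 48-89%,
#' 11/19 -> 36-80%).
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param z normal quantile, default 1.96.
#' @return list with `low` and `high` integer percent bounds.
#' @export
wald_ci <- function(successes, n, z = 1.96) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  p <- successes / n
  half <- z * sqrt(p * (1 - p) / n)
  list(low = round_half_up(max(0, p - half) * 100),
       high = round_half_up(min(1, p + half) * 100))
}

#' Bland-Altman agreement statistics with Pearson correlation
#'
#' For paired measurements (a, b) — e.g. two raters' ROI areas — computes
#' the bias `mean(a - b)`, the 95% limits of agreement
#' `bias +/- 1.96 sd(a - b)` (sample sd, n - 1), and the Pearson correlation
#' of a with b. When both samples are constant the correlation is undefined
#' and reported as NA.
#'
#' @param a,b equal-length numeric vectors, n >= 2.
#' @return list with `bias`, `loa_low`, `loa_high`, `pearson_r`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length",
                                   call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(a, b)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       pearson_r = r, n = length(a))
}

#' Recompute the clinical table's clustering metrics
#'
#' For each of the six ROI-method x distance-metric label columns of the
#' packaged clinical table, computes the weighted F-score (rounded to the
#' 2-decimal printed precision) and the direct-match accuracy (integer
#' percent, labels compared as printed, i.e. without realignment) against
#' the clinical reference, plus the Wald 95% CI of the accuracy.
#'
#' @param tab the clinical table; defaults to [load_table1()].
#' @return data.frame with one row per column: `column`, `roi_method`,
#'   `metric`, `f_score` (2 decimals), `accuracy_percent`, `ci_low`,
#'   `ci_high`, `n_match`.
#' @export
reproduce_table1 <- function(tab = load_table1()) {
  cols <- c("ME", "MC", "SE", "SC", "AE", "AC")
  methods <- c(ME = "manual", MC = "manual", SE = "semiauto", SC = "semiauto",
               AE = "auto", AC = "auto")
  metrics <- c(ME = "euclidean", MC = "cosine", SE = "euclidean",
               SC = "cosine", AE = "euclidean", AC = "cosine")
  rows <- lapply(cols, function(cl) {
    f <- clustering_f_score(tab$clinical, tab[[cl]])
    acc <- accuracy(tab$clinical, tab[[cl]], align = FALSE)
    ci <- wald_ci(acc$n_match, acc$n)
    data.frame(column = cl, roi_method = methods[[cl]], metric = metrics[[cl]],
               f_score = round_half_up(f, 2),
               accuracy_percent = acc$percent,
               ci_low = ci$low, ci_high = ci$high,
               n_match = acc$n_match)
  })
  do.call(rbind, rows)
}
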