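#' Dice overlap coefficient between two binary masks
#'
#' `Dice(A, B) = 2|A∩B| / (|A| + |B|)`; symmetric, 1 for identical masks,
#' 0 for disjoint ones. Defined as 1 when both masks are empty.
#'
#' @param a,b Binary mask matrices of identical dimensions.
#' @return Fraction in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Hausdorff distance between two binary masks
#'
#' Maximum of the two directed Hausdorff distances between the boundary
#' pixel sets (4-neighbor boundaries, Euclidean metric, pixel units). The
#' classic max-min form, not a percentile variant. Undefined (`NA`) when
#' either mask is empty.
#'
#' @param a,b Binary mask matrices of identical dimensions.
#' @return Distance in pixels, or `NA_real_` if either mask is empty.
#' @export
hausdorff_distance <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  pa <- which(boundary_pixels(a != 0), arr.ind = TRUE)
  pb <- which(boundary_pixels(b != 0), arr.ind = TRUE)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(NA_real_)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2 <- pmax(d2, 0)
  # max of the two directed max-min distances
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

#' Sensitivity and specificity of a segmentation
#'
#' Sensitivity = 100·TP/(TP+FN) over ground-truth-positive pixels;
#' specificity = 100·TN/(TN+FP) over all ground-truth-negative pixels of
#' the slice, black background included. Sensitivity is `NA` when the
#' ground truth is empty.
#'
#' @param pred Predicted binary mask.
#' @param gt Ground-truth binary mask, same dimensions.
#' @return Named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
sensitivity_specificity <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("mask dimensions differ")
  p <- pred != 0; g <- gt != 0
  tp <- sum(p & g); fn <- sum(!p & g)
  tn <- sum(!p & !g); fp <- sum(p & !g)
  sens <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  c(sensitivity = sens, specificity = spec)
}

#' All four segmentation metrics for one mask pair
#'
#' @param pred Predicted binary mask.
#' @param gt Ground-truth binary mask.
#' @return Data frame with one row: `dice`, `hd`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_masks <- function(pred, gt) {
  ss <- sensitivity_specificity(pred, gt)
  data.frame(dice = dice(pred, gt), hd = hausdorff_distance(pred, gt),
             sensitivity = ss[["sensitivity"]],
             specificity = ss[["specificity"]])
}

#' Cohort summary of segmentation metrics (mean ± sd per group)
#'
#' @param metrics Data frame with columns `dice`, `hd`, `sensitivity`,
#'   `specificity` (one row per case).
#' @param group Optional vector of group labels (e.g. tumor grade); an
#'   `ALL` row is always appended.
#' @return Data frame: `group`, `n`, then `<metric>_mean` and
#'   `<metric>_sd` for each metric. The sd of a single entry is 0.
#' @export
summarize_cohort <- function(metrics, group = NULL) {
  stopifnot(nrow(metrics) >= 1L)
  cols <- c("dice", "hd", "sensitivity", "specificity")
  cols <- intersect(cols, names(metrics))
  one <- function(rows, label) {
    m <- metrics[rows, cols, drop = FALSE]
    out <- data.frame(group = label, n = nrow(m))
    for (cl in cols) {
      v <- m[[cl]][!is.na(m[[cl]])]
      out[[paste0(cl, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(cl, "_sd")]] <- if (length(v) > 1) sd(v) else 0
    }
    out
  }
  rows <- list()
  if (!is.null(group)) {
    for (g in sort(unique(group)))
      rows[[length(rows) + 1L]] <- one(which(group == g), as.character(g))
  }
  rows[[length(rows) + 1L]] <- one(seq_len(nrow(metrics)), "ALL")
  do.call(rbind, rows)
}
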