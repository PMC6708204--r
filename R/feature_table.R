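#' Canonical names of the 69 per-superpixel features
#'
#' 17 intensity statistics, 13 Haralick features on each of the gray-level
#' (GLCM), gradient (GLGCM) and curvature (GLCCM) co-occurrence matrices,
#' 1 mean curvature, and 12 fractal features: 17 + 39 + 1 + 12 = 69.
#'
#' @return Character vector of length 69 in canonical order.
#' @export
feature_names <- function() {
  stat_names <- c("energy", "entropy", "minimum", "maximum", "mean", "median",
                  "range", "sd", "variance", "mad", "rms", "skewness",
                  "kurtosis", "uniformity", "p10", "p90", "iqr")
  har <- c("asm", "contrast", "correlation", "variance", "idm", "sum_average",
           "sum_variance", "sum_entropy", "entropy", "difference_variance",
           "difference_entropy", "imc1", "imc2")
  frac <- as.vector(vapply(1:4, function(k)
    paste0("fractal_c", k, "_", c("area", "brightness", "boxdim")),
    character(3)))
  c(paste0("int_", stat_names),
    paste0("glcm_", har), paste0("glgcm_", har), paste0("glccm_", har),
    "curvature_mean", frac)
}

#' Superpixels retained after background removal
#'
#' Superpixels whose mean intensity is below the background threshold are
#' black background around the head: they are excluded from feature
#' extraction and forced non-tumor in the final mask. The comparison is
#' strict (`mean < threshold` removes; `mean == threshold` retains).
#'
#' @param image Numeric intensity matrix.
#' @param sp A `superpixel_map`.
#' @param threshold Mean-intensity threshold (default 5, on the 12-bit
#'   scale).
#' @return Integer vector of retained 0-based superpixel ids.
#' @export
remove_background_superpixels <- function(image, sp, threshold = 5) {
  stopifnot(identical(dim(image), dim(sp$labels)))
  sizes <- tabulate(sp$labels + 1L, nbins = sp$count)
  sums <- as.vector(rowsum(as.vector(image), as.vector(sp$labels)))
  means <- sums / sizes
  which(means >= threshold) - 1L
}

#' Extract the 69-feature table for every retained superpixel
#'
#' For each retained superpixel: first-order intensity statistics on its
#' raw pixels; 13 Haralick features per source image (original intensities
#' for the GLCM, Roberts gradient map for the GLGCM, Prewitt map for the
#' GLCCM), each averaged over the 4 directions (0/45/90/135 degrees, offset
#' 1) and the 4 quantization levels (8/16/32/64); the mean per-pixel
#' curvature; and 12 fractal features over the slice-level Otsu channels.
#' Quantization is per superpixel (its own min/max), and co-occurrence
#' pairs never cross a superpixel boundary.
#'
#' @param image Numeric intensity matrix.
#' @param sp A `superpixel_map` over the same lattice.
#' @param retained Integer vector of 0-based superpixel ids to process
#'   (default: all ids; see [remove_background_superpixels()]).
#' @param levels Quantization levels (default `c(8, 16, 32, 64)`).
#' @param directions Co-occurrence directions in degrees (default
#'   `c(0, 45, 90, 135)`).
#' @param fg_threshold Foreground threshold for the Otsu channels
#'   (default 5).
#' @return Data frame: column `id` plus the 69 columns of
#'   [feature_names()], one row per retained superpixel.
#' @export
extract_feature_table <- function(image, sp, retained = NULL,
                                  levels = c(8L, 16L, 32L, 64L),
                                  directions = c(0, 45, 90, 135),
                                  fg_threshold = 5) {
  stopifnot(identical(dim(image), dim(sp$labels)))
  if (is.null(retained)) retained <- seq_len(sp$count) - 1L
  retained <- sort(unique(as.integer(retained)))
  M <- length(retained)
  if (M == 0L) stop("no retained superpixels")
  h <- nrow(image); w <- ncol(image)
  lab <- as.vector(sp$labels)
  # position of each pixel's label within `retained` (NA: not retained)
  lab_pos <- match(lab, retained)

  sources <- list(glcm = image,
                  glgcm = roberts_gradient_map(image),
                  glccm = prewitt_curvature_map(image))

  pix_by_sp <- split(seq_along(lab), factor(lab_pos, levels = seq_len(M)))

  # --- intensity statistics -------------------------------------------------
  stats17 <- t(vapply(pix_by_sp, function(ix) intensity_statistics(image[ix]),
                      numeric(17)))

  # --- Haralick features on GLCM / GLGCM / GLCCM ---------------------------
  # all (pixel, pixel+offset) pairs with both ends in the same retained
  # superpixel, accumulated per superpixel in one vectorized pass per
  # (source, level, direction) combination
  pair_idx <- lapply(directions, function(d) {
    off <- glcm_offset(d)
    rr <- seq_len(h); cc <- seq_len(w)
    ok_r <- rr + off[1] >= 1L & rr + off[1] <= h
    ok_c <- cc + off[2] >= 1L & cc + off[2] <= w
    i1 <- outer(rr[ok_r], (cc[ok_c] - 1L) * h, `+`)
    i2 <- outer(rr[ok_r] + off[1], (cc[ok_c] + off[2] - 1L) * h, `+`)
    keep <- !is.na(lab_pos[i1]) & lab_pos[i1] == lab_pos[i2]
    list(i1 = i1[keep], i2 = i2[keep])
  })

  har <- lapply(names(sources), function(sname) {
    x <- as.vector(sources[[sname]])
    # per-superpixel min / range of this source
    mins <- vapply(pix_by_sp, function(ix) min(x[ix]), numeric(1))
    maxs <- vapply(pix_by_sp, function(ix) max(x[ix]), numeric(1))
    rng <- maxs - mins
    acc <- matrix(0, M, 13)
    for (L in levels) {
      q <- integer(length(x))
      pos_ok <- !is.na(lab_pos)
      xx <- x[pos_ok]; pp <- lab_pos[pos_ok]
      qq <- ifelse(rng[pp] > 0,
                   pmin(floor((xx - mins[pp]) / rng[pp] * L), L - 1), 0)
      q[pos_ok] <- as.integer(qq)
      for (pd in pair_idx) {
        idx <- (lab_pos[pd$i1] - 1L) * L * L + q[pd$i1] * L + q[pd$i2] + 1L
        tab <- tabulate(idx, nbins = M * L * L)
        idx2 <- (lab_pos[pd$i1] - 1L) * L * L + q[pd$i2] * L + q[pd$i1] + 1L
        tab <- tab + tabulate(idx2, nbins = M * L * L)
        for (m in seq_len(M)) {
          cm <- matrix(tab[((m - 1L) * L * L + 1L):(m * L * L)], L, L,
                       byrow = TRUE)
          tot <- sum(cm)
          if (tot > 0) acc[m, ] <- acc[m, ] + cpp_haralick(cm / tot)
        }
      }
    }
    acc / (length(levels) * length(directions))
  })
  names(har) <- names(sources)

  # --- curvature ------------------------------------------------------------
  curv <- curvature_map(image)
  curv_mean <- vapply(pix_by_sp, function(ix) mean(curv[ix]), numeric(1))

  # --- fractal --------------------------------------------------------------
  channels <- otsu_channels(image, fg_threshold = fg_threshold)
  frac <- t(vapply(pix_by_sp, function(ix) {
    region <- matrix(FALSE, h, w); region[ix] <- TRUE
    fractal_features(image, region, channels)
  }, numeric(12)))

  out <- data.frame(id = retained,
                    stats17, har$glcm, har$glgcm, har$glccm,
                    curvature_mean = curv_mean, frac)
  colnames(out) <- c("id", feature_names())
  rownames(out) <- NULL
  out
}
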