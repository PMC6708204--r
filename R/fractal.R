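#' Multi-level Otsu channel decomposition
#'
#' Three thresholds chosen by exhaustive maximization of the between-class
#' variance of the foreground histogram (intensity >= `fg_threshold`)
#' split the foreground into four intensity intervals. Channel k is the
#' binary mask of interval k; its edge image marks channel pixels with at
#' least one 4-neighbor outside the channel (the image border counts as
#' outside). Channels partition the foreground. Thresholding is done once
#' per slice on the whole-slice foreground.
#'
#' @param image Numeric intensity matrix.
#' @param n_channels Number of channels (fixed default 4).
#' @param fg_threshold Foreground intensity threshold (default 5).
#' @return List of class `fractal_channels`: `channels` and `edges` (lists
#'   of logical matrices), `thresholds`, `degenerate` (too few distinct
#'   foreground values; all downstream features become 0).
#' @export
otsu_channels <- function(image, n_channels = 4L, fg_threshold = 5) {
  fg <- image >= fg_threshold
  vals <- image[fg]
  distinct <- unique(vals)
  if (length(distinct) < n_channels) {
    empty <- matrix(FALSE, nrow(image), ncol(image))
    return(structure(list(channels = rep(list(empty), n_channels),
                          edges = rep(list(empty), n_channels),
                          thresholds = numeric(0), degenerate = TRUE),
                     class = "fractal_channels"))
  }
  thr <- multi_otsu_thresholds(vals, n_channels - 1L)
  channels <- vector("list", n_channels)
  lo <- -Inf
  for (k in seq_len(n_channels)) {
    hi <- if (k < n_channels) thr[k] else Inf
    channels[[k]] <- fg & image > lo & image <= hi
    lo <- hi
  }
  structure(list(channels = channels,
                 edges = lapply(channels, boundary_pixels),
                 thresholds = thr, degenerate = FALSE),
            class = "fractal_channels")
}

# exhaustive multi-level Otsu: maximize sum_k w_k * mu_k^2 over cut points
# of the value histogram (equivalent to maximizing between-class variance)
multi_otsu_thresholds <- function(vals, n_thresholds) {
  u <- sort(unique(vals))
  if (length(u) > 256L) {
    # bin to 256 equal-width levels for tractability
    rng <- range(vals)
    edges <- seq(rng[1], rng[2], length.out = 257L)
    mids <- (edges[-1] + edges[-257L]) / 2
    b <- pmin(floor((vals - rng[1]) / (rng[2] - rng[1]) * 256), 255) + 1L
    cnt <- tabulate(b, nbins = 256L)
    keep <- cnt > 0
    u <- mids[keep]; cnt <- cnt[keep]
  } else {
    cnt <- tabulate(match(vals, u), nbins = length(u))
  }
  B <- length(u)
  stopifnot(n_thresholds == 3L, B >= 4L)
  cw <- cumsum(cnt)
  cs <- cumsum(cnt * u)
  # class (a, b]: weight/sum via cumulative differences (1-based bin ids)
  wsum <- function(a, b) cw[b] - if (a >= 1L) cw[a] else 0
  vsum <- function(a, b) cs[b] - if (a >= 1L) cs[a] else 0
  best <- -Inf; best_t <- c(1L, 2L, 3L)
  for (t1 in 1L:(B - 3L)) {
    w1 <- wsum(0L, t1); m1 <- vsum(0L, t1)
    s1 <- if (w1 > 0) m1^2 / w1 else 0
    for (t2 in (t1 + 1L):(B - 2L)) {
      w2 <- wsum(t1, t2); m2 <- vsum(t1, t2)
      s2 <- if (w2 > 0) m2^2 / w2 else 0
      t3 <- (t2 + 1L):(B - 1L)
      w3 <- cw[t3] - cw[t2]; m3 <- cs[t3] - cs[t2]
      w4 <- cw[B] - cw[t3]; m4 <- cs[B] - cs[t3]
      s34 <- ifelse(w3 > 0, m3^2 / w3, 0) + ifelse(w4 > 0, m4^2 / w4, 0)
      tot <- s1 + s2 + s34
      i <- which.max(tot)
      if (tot[i] > best) {
        best <- tot[i]
        best_t <- c(t1, t2, t3[i])
      }
    }
  }
  u[best_t]
}

# mask pixels with >= 1 of their 4-neighbors outside the mask (image
# border counts as outside)
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  mask & !inner
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts boxes of size 1, 2, 4, 8, 16 and 32 px (anchored at the image
#' origin) that contain at least one mask pixel, and returns the slope of
#' the least-squares fit of log(count) against log(1/size). A straight
#' line scores near 1, a filled region near 2; an empty mask returns 0.
#'
#' @param binary Logical or 0/1 mask matrix.
#' @param sizes Box sizes (default `2^(0:5)`).
#' @return Scalar dimension estimate.
#' @export
box_counting_dimension <- function(binary, sizes = 2^(0:5)) {
  coords <- which(binary != 0, arr.ind = TRUE)
  box_count_dim_coords(coords[, 1], coords[, 2], sizes)
}

box_count_dim_coords <- function(rows, cols, sizes = 2^(0:5)) {
  if (length(rows) == 0L) return(0)
  counts <- vapply(sizes, function(s) {
    br <- (rows - 1L) %/% s
    bc <- (cols - 1L) %/% s
    length(unique(br * (max(bc) + 1L) + bc))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / sizes))
  unname(coef(fit)[2])
}

#' The 12 fractal features of a region
#'
#' For each of the 4 Otsu channels restricted to the region: area in
#' pixels, mean original brightness over the intersection (0 if empty),
#' and the box-counting dimension of the channel's edge image restricted
#' to the region. Degenerate channel sets yield 12 zeros.
#'
#' @param image Numeric intensity matrix (original intensities).
#' @param region Logical matrix selecting the region.
#' @param channels A `fractal_channels` from [otsu_channels()].
#' @return Named numeric vector of length 12, ordered
#'   `c1_area, c1_brightness, c1_boxdim, ..., c4_boxdim`.
#' @export
fractal_features <- function(image, region, channels) {
  n <- length(channels$channels)
  out <- numeric(3L * n)
  names(out) <- as.vector(vapply(seq_len(n), function(k)
    paste0("c", k, "_", c("area", "brightness", "boxdim")), character(3)))
  if (channels$degenerate) return(out)
  for (k in seq_len(n)) {
    inter <- channels$channels[[k]] & region
    area <- sum(inter)
    out[3L * k - 2L] <- area
    out[3L * k - 1L] <- if (area > 0) mean(image[inter]) else 0
    out[3L * k] <- box_counting_dimension(channels$edges[[k]] & region)
  }
  out
}
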