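#' The 17 first-order intensity statistics
#'
#' Histogram-based first-order features of a pixel set, in canonical
#' order: energy, entropy, minimum, maximum, mean, median, range, standard
#' deviation, variance, mean absolute deviation, root mean square,
#' skewness, kurtosis, uniformity, 10th percentile, 90th percentile,
#' interquartile range. Entropy (bits) and uniformity are computed on a
#' 64-bin histogram over the pixel range. Skewness and kurtosis use
#' population moments (kurtosis of a normal sample is near 3) and are
#' defined as 0 for constant input.
#'
#' @param pixels Numeric vector of intensities (non-empty).
#' @return Named numeric vector of length 17.
#' @export
intensity_statistics <- function(pixels) {
  if (length(pixels) == 0) stop("empty pixel set")
  x <- as.numeric(pixels)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p <- histogram_probs(x, bins = 64L)
  eps <- 1e-12
  s <- if (n > 1) sd(x) else 0
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  c(energy = sum(x^2),
    entropy = -sum(p * log2(p + eps)),
    minimum = min(x),
    maximum = max(x),
    mean = mu,
    median = median(x),
    range = max(x) - min(x),
    sd = s,
    variance = if (n > 1) var(x) else 0,
    mad = mean(abs(x - mu)),
    rms = sqrt(mean(x^2)),
    skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    uniformity = sum(p^2),
    p10 = q[1],
    p90 = q[4],
    iqr = q[3] - q[2])
}

histogram_probs <- function(x, bins = 64L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(1)
  b <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * bins), bins - 1L)
  tabulate(b + 1L, nbins = bins) / length(x)
}

#' Quantize intensities of a region to discrete gray levels
#'
#' Linear binning of the region's intensity range [min, max] into
#' `{0, ..., levels-1}`; a constant region maps entirely to level 0.
#' Texture features on 12-bit MRI use levels 8, 16, 32 and 64.
#'
#' @param image Numeric intensity matrix.
#' @param levels Number of gray levels (>= 2).
#' @param region Logical matrix selecting the region (default: whole
#'   image).
#' @return Integer matrix of levels, `NA` outside the region.
#' @export
quantize_gray <- function(image, levels, region = NULL) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (is.null(region)) region <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(region)) stop("empty region")
  x <- image[region]
  rng <- range(x)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (rng[1] == rng[2]) {
    q[region] <- 0L
  } else {
    q[region] <- pmin(as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * levels)),
                      levels - 1L)
  }
  q
}

glcm_offset <- function(direction) {
  switch(as.character(direction),
         "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix of a region
#'
#' Counts symmetric pairs of quantized gray levels at a 1-pixel offset in
#' one of the four canonical directions (0, 45, 90, 135 degrees); both
#' pixels of a pair must lie inside the region. The normalized copy sums
#' to 1 and is the input to [haralick_features()].
#'
#' @param quantized Integer level matrix as returned by [quantize_gray()]
#'   (`NA` outside the region).
#' @param levels Number of gray levels L.
#' @param direction One of 0, 45, 90, 135.
#' @return List of class `cooccurrence`: `counts` (L x L), `prob`
#'   (normalized), `direction`, `empty` (no valid pair).
#' @export
cooccurrence_matrix <- function(quantized, levels, direction) {
  off <- glcm_offset(direction)
  h <- nrow(quantized); w <- ncol(quantized)
  r1 <- seq_len(h); c1 <- seq_len(w)
  r2 <- r1 + off[1]; c2 <- c1 + off[2]
  ok_r <- r2 >= 1L & r2 <= h; ok_c <- c2 >= 1L & c2 <= w
  a <- quantized[r1[ok_r], c1[ok_c], drop = FALSE]
  b <- quantized[r2[ok_r], c2[ok_c], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  counts <- matrix(0, levels, levels)
  if (any(keep)) {
    idx <- a[keep] * levels + b[keep] + 1L
    tab <- tabulate(idx, nbins = levels * levels)
    counts <- matrix(tab, levels, levels, byrow = TRUE)
    counts <- counts + t(counts)  # symmetric: count both orders
  }
  total <- sum(counts)
  structure(list(counts = counts,
                 prob = if (total > 0) counts / total else counts,
                 direction = direction, empty = total == 0),
            class = "cooccurrence")
}

#' The 13 classic Haralick texture features
#'
#' Angular second moment, contrast, correlation, sum of squares (variance),
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, and the two
#' information measures of correlation, computed from a normalized
#' co-occurrence matrix. Entropies are in bits; all log arguments are
#' guarded with eps = 1e-12 so every value is finite. Sum variance is taken
#' about the sum average. The unstable 14th feature (maximal correlation
#' coefficient) is omitted. An empty matrix yields 13 zeros.
#'
#' @param matrix A `cooccurrence` object or a normalized L x L matrix.
#' @return Named numeric vector of length 13.
#' @export
haralick_features <- function(matrix) {
  p <- if (inherits(matrix, "cooccurrence")) matrix$prob else matrix
  cpp_haralick(p)
}

#' Roberts gradient magnitude map
#'
#' Per-pixel magnitude of the two 2x2 Roberts cross kernels (diagonal
#' differences), with edge replication at the border. Feeds the gray-level
#' gradient co-occurrence matrix (GLGCM).
#'
#' @param image Numeric intensity matrix.
#' @return Matrix of gradient magnitudes, same size.
#' @export
roberts_gradient_map <- function(image) {
  h <- nrow(image); w <- ncol(image)
  rp <- c(2:h, h); cp <- c(2:w, w)  # replicated +1 indices
  g1 <- image - image[rp, cp]
  g2 <- image[, cp] - image[rp, ]
  sqrt(g1^2 + g2^2)
}

#' Prewitt gradient magnitude map
#'
#' Per-pixel magnitude of the two 3x3 Prewitt kernels, with edge
#' replication at the border. This map feeds the gray-level curvature
#' co-occurrence matrix (GLCCM); it is distinct from the mean-curvature
#' feature of [curvature_map()].
#'
#' @param image Numeric intensity matrix.
#' @return Matrix of magnitudes, same size.
#' @export
prewitt_curvature_map <- function(image) {
  h <- nrow(image); w <- ncol(image)
  rm1 <- c(1, 1:(h - 1)); rp1 <- c(2:h, h)
  cm1 <- c(1, 1:(w - 1)); cp1 <- c(2:w, w)
  px <- (image[rm1, cp1] + image[, cp1] + image[rp1, cp1]) -
    (image[rm1, cm1] + image[, cm1] + image[rp1, cm1])
  py <- (image[rp1, cm1] + image[rp1, ] + image[rp1, cp1]) -
    (image[rm1, cm1] + image[rm1, ] + image[rm1, cp1])
  sqrt(px^2 + py^2)
}

#' Per-pixel curvature map
#'
#' Central-difference first and second derivatives feed the curvature
#' expression
#' \deqn{Curv = (f_{xx} f_y^2 + f_{yy} f_x^2 - 2 f_{xx} f_x f_y) /
#'       (f_x^2 + f_y^2)^{3/2}.}
#' Note the cross term deliberately carries \eqn{f_{xx}} (not the
#' textbook \eqn{f_{xy}}): this asymmetric form is the definition of the
#' curvature index used throughout the package. Pixels with
#' a degenerate gradient (\eqn{f_x^2 + f_y^2 < 10^{-8}}) get curvature 0.
#' x runs along columns, y along rows; borders are edge-replicated.
#'
#' @param image Numeric intensity matrix.
#' @return Matrix of per-pixel curvature values.
#' @export
curvature_map <- function(image) {
  h <- nrow(image); w <- ncol(image)
  rm1 <- c(1, 1:(h - 1)); rp1 <- c(2:h, h)
  cm1 <- c(1, 1:(w - 1)); cp1 <- c(2:w, w)
  fx <- (image[, cp1] - image[, cm1]) / 2
  fy <- (image[rp1, ] - image[rm1, ]) / 2
  fxx <- image[, cp1] - 2 * image + image[, cm1]
  fyy <- image[rp1, ] - 2 * image + image[rm1, ]
  g2 <- fx^2 + fy^2
  curv <- matrix(0, h, w)
  ok <- g2 >= 1e-8
  curv[ok] <- (fxx[ok] * fy[ok]^2 + fyy[ok] * fx[ok]^2 -
                 2 * fxx[ok] * fx[ok] * fy[ok]) / g2[ok]^1.5
  curv
}

#' Mean curvature of a region
#'
#' Average of the [curvature_map()] values over the region; the curvature
#' feature of a superpixel.
#'
#' @param image Numeric intensity matrix.
#' @param region Logical matrix selecting the region (non-empty).
#' @return Scalar.
#' @export
curvature_feature <- function(image, region) {
  if (!any(region)) stop("empty region")
  mean(curvature_map(image)[region])
}
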