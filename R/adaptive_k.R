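#' Shift an image horizontally (zero fill)
#'
#' @param image Numeric matrix.
#' @param shift Signed column shift in pixels; positive moves content right.
#' @return Shifted matrix of the same size.
#' @export
shift_horizontal <- function(image, shift) {
  w <- ncol(image)
  out <- matrix(0, nrow(image), w)
  if (shift >= 0) {
    if (shift < w) out[, (shift + 1):w] <- image[, 1:(w - shift)]
  } else {
    s <- -shift
    if (s < w) out[, 1:(w - s)] <- image[, (s + 1):w]
  }
  out
}

#' Rotate an image about its center (bilinear, zero fill)
#'
#' @param image Numeric matrix.
#' @param degrees Signed rotation angle in degrees (counter-clockwise in
#'   row/col space).
#' @return Rotated matrix of the same size.
#' @export
rotate_image <- function(image, degrees) {
  if (degrees == 0) return(image)
  h <- nrow(image); w <- ncol(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  rr <- matrix(seq_len(h), h, w) - cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse mapping: source coordinates for each output pixel
  sr <- co * rr + si * cc + cy
  sc <- -si * rr + co * cc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  at <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- numeric(length(r))
    v[ok] <- image[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * at(r0, c0) + (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) + fr * fc * at(r0 + 1, c0 + 1)
  matrix(v, h, w)
}

mirror_correlation <- function(image) {
  w <- ncol(image)
  half <- w %/% 2
  left <- as.vector(image[, 1:half])
  right <- as.vector(image[, w:(w - half + 1)])
  if (sd(left) == 0 || sd(right) == 0) return(-Inf)
  cor(left, right)
}

#' Align the brain midline by exhaustive symmetry search
#'
#' Searches horizontal shifts in [-20, 20] px and rotations in [-10, 10]
#' degrees (step 1 each) for the transform that maximizes the Pearson
#' correlation between the left half of the corrected image and the
#' mirrored right half. The search visits small transforms first, so on an
#' already-symmetric image the identity wins ties and shift = rotation = 0.
#'
#' @param image Numeric intensity matrix with some foreground (>= 5).
#' @param max_shift,max_rotation Search half-ranges (defaults 20 px, 10
#'   degrees).
#' @return A list of class `symmetry_alignment`: `shift`, `rotation`,
#'   `corrected` (the transformed image), and `score` (the achieved
#'   correlation).
#' @export
align_midline <- function(image, max_shift = 20L, max_rotation = 10L) {
  if (!any(image >= 5)) stop("all-background image: no foreground to align")
  # visit candidates in order of increasing magnitude so ties keep the
  # smallest transform
  by_mag <- function(k) { v <- -k:k; v[order(abs(v), v)] }
  best <- list(score = -Inf)
  for (rot in by_mag(max_rotation)) {
    rotated <- rotate_image(image, rot)
    for (sh in by_mag(max_shift)) {
      corrected <- shift_horizontal(rotated, sh)
      score <- mirror_correlation(corrected)
      if (score > best$score)
        best <- list(shift = sh, rotation = rot, corrected = corrected,
                     score = score)
    }
  }
  structure(best[c("shift", "rotation", "corrected", "score")],
            class = "symmetry_alignment")
}

#' Hemispheric grid similarity map
#'
#' Divides a (resampled-to-)240x240 corrected slice into 16 x 16 cells of
#' 15 x 15 px and computes, for every cell and its mirror-image cell in
#' the opposite hemisphere, the Pearson correlation of the 225 paired
#' pixels. Zero-variance cells (flat background) are flagged undefined and
#' treated as perfectly symmetric (r = 1) so that background never inflates
#' the tumor area ratio.
#'
#' @param corrected Corrected (midline-aligned) intensity matrix.
#' @return List of class `grid_similarity`: `r_values` (16x16 matrix),
#'   `undefined` (16x16 logical), `cell_size` (15).
#' @export
grid_similarity <- function(corrected) {
  corrected <- resample_to(corrected, 240L, 240L)
  n_cells <- 16L; cs <- 15L; w <- 240L
  r_values <- matrix(1, n_cells, n_cells)
  undefined <- matrix(FALSE, n_cells, n_cells)
  for (i in seq_len(n_cells)) {
    rows <- ((i - 1L) * cs + 1L):(i * cs)
    for (j in seq_len(n_cells %/% 2L)) {
      cols <- ((j - 1L) * cs + 1L):(j * cs)
      a <- corrected[rows, cols]
      b <- corrected[rows, (w + 1L) - cols]  # mirrored pairing
      if (sd(a) == 0 || sd(b) == 0) {
        undefined[i, j] <- undefined[i, n_cells + 1L - j] <- TRUE
        r <- 1
      } else {
        r <- cor(as.vector(a), as.vector(b))
      }
      r_values[i, j] <- r_values[i, n_cells + 1L - j] <- r
    }
  }
  structure(list(r_values = r_values, undefined = undefined, cell_size = cs),
            class = "grid_similarity")
}

# bilinear resampling to a fixed lattice (used only for the TAR/TC grid)
resample_to <- function(image, h2, w2) {
  h <- nrow(image); w <- ncol(image)
  if (h == h2 && w == w2) return(image)
  sr <- (seq_len(h2) - 0.5) * h / h2 + 0.5
  sc <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  r0 <- pmin(pmax(floor(sr), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(sc), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
  top <- image[r0, c0] * outer(1 - fr, 1 - fc) + image[r0, c1] * outer(1 - fr, fc)
  bot <- image[r1, c0] * outer(fr, 1 - fc) + image[r1, c1] * outer(fr, fc)
  top + bot
}

#' Flag asymmetric grid cells as suspected tumor area
#'
#' Cells whose similarity falls below the threshold are flagged; the
#' returned mask is the union of the flagged left-hemisphere cell
#' footprints and `n_blocks` counts the flagged left-hemisphere cells.
#'
#' @param sim A `grid_similarity`.
#' @param threshold Similarity threshold (default 0.81).
#' @return List: `mask` (240x240 binary), `n_blocks`, `flagged` (16x16
#'   logical).
#' @export
flag_suspected_blocks <- function(sim, threshold = 0.81) {
  flagged <- sim$r_values < threshold
  n_cells <- nrow(flagged); cs <- sim$cell_size
  half <- n_cells %/% 2L
  mask <- matrix(0L, n_cells * cs, n_cells * cs)
  n_blocks <- 0L
  for (i in seq_len(n_cells)) {
    for (j in seq_len(half)) {
      if (flagged[i, j]) {
        n_blocks <- n_blocks + 1L
        mask[((i - 1L) * cs + 1L):(i * cs), ((j - 1L) * cs + 1L):(j * cs)] <- 1L
      }
    }
  }
  list(mask = mask, n_blocks = n_blocks, flagged = flagged)
}

#' Tumor area ratio
#'
#' `TAR = n / 256`: the fraction of the 256 hemispheric grid cells flagged
#' asymmetric, a proxy for tumor size.
#'
#' @param n_blocks Count of flagged left-hemisphere cells, in [0, 256].
#' @return Fraction in [0, 1].
#' @export
compute_tar <- function(n_blocks) {
  if (n_blocks < 0 || n_blocks > 256) stop("n_blocks must be in [0, 256]")
  n_blocks / 256
}

#' Tumor boundary complexity
#'
#' `TC = N(edge) / N(area)`: boundary pixel count over area pixel count of
#' the suspected tumor mask. A boundary pixel is a mask pixel with at least
#' one 4-neighbor outside the mask (the image border counts as outside).
#' Returns 0 for an empty mask.
#'
#' @param suspected Binary mask matrix.
#' @return Non-negative scalar.
#' @export
compute_tc <- function(suspected) {
  area <- sum(suspected != 0)
  if (area == 0) return(0)
  sum(boundary_pixels(suspected != 0)) / area
}

#' Compute the (TAR, TC) tumor descriptor of a slice
#'
#' Convenience wrapper: midline alignment, grid similarity, block flagging,
#' TAR and TC in one call.
#'
#' @param image Numeric intensity matrix.
#' @param similarity_threshold Cell-similarity threshold (default 0.81).
#' @return List of class `tumor_descriptor`: `tar`, `tc`, `n_blocks`,
#'   `alignment`, `suspected` (the flagged-cell mask).
#' @export
tumor_descriptor <- function(image, similarity_threshold = 0.81) {
  al <- align_midline(image)
  sim <- grid_similarity(al$corrected)
  fl <- flag_suspected_blocks(sim, similarity_threshold)
  structure(list(tar = compute_tar(fl$n_blocks), tc = compute_tc(fl$mask),
                 n_blocks = fl$n_blocks, alignment = al, suspected = fl$mask),
            class = "tumor_descriptor")
}

#' Label the best superpixel count K from ground truth
#'
#' For every K on the search grid, runs SLIC0, merges superpixels whose
#' overlap fraction with the ground truth exceeds `merge_ratio` into a
#' candidate region A, and scores Dice(A, ground truth). Dice(K) typically
#' rises to a broad plateau; the returned K is the (lower) median of the
#' longest contiguous run of K values within `plateau_epsilon` of the best
#' Dice — an automated version of picking K "in the middle" of the good
#' range, which is robust for unseen slices.
#'
#' @param image Numeric intensity matrix.
#' @param gt Binary ground-truth mask (non-empty).
#' @param k_grid Candidate K values (default 10, 20, ..., 450).
#' @param merge_ratio Overlap fraction above which a superpixel joins A
#'   (default 0.9).
#' @param plateau_epsilon Dice tolerance defining the plateau (default 0.01).
#' @param iterations SLIC0 iterations (default 10).
#' @return Integer K (attribute `"dice"` carries the per-K Dice curve).
#' @export
label_best_k <- function(image, gt, k_grid = seq(10L, 450L, 10L),
                         merge_ratio = 0.9, plateau_epsilon = 0.01,
                         iterations = 10L) {
  assert_mask(gt, image)
  if (sum(gt) == 0) stop("ground truth is empty")
  dice_k <- vapply(k_grid, function(K) {
    sp <- run_slic0(image, K, iterations = iterations)
    a <- merge_overlapping_superpixels(sp, gt, merge_ratio)
    dice(a, gt)
  }, numeric(1))
  d_max <- max(dice_k)
  good <- dice_k >= d_max - plateau_epsilon
  run <- longest_run(good)
  ks <- k_grid[run]
  k <- ks[ceiling(length(ks) / 2)]
  attr(k, "dice") <- stats::setNames(dice_k, k_grid)
  k
}

# union of superpixels whose overlap fraction with gt exceeds merge_ratio
merge_overlapping_superpixels <- function(sp, gt, merge_ratio) {
  sizes <- tabulate(sp$labels + 1L, nbins = sp$count)
  inside <- tabulate(sp$labels[gt != 0] + 1L, nbins = sp$count)
  keep <- which(inside / sizes > merge_ratio) - 1L
  matrix(as.integer(sp$labels %in% keep), nrow(gt), ncol(gt))
}

# indices of the longest contiguous TRUE run (first on ties)
longest_run <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  starts[best]:ends[best]
}

#' Train the random-forest K predictor
#'
#' A 5-tree regression forest maps (TAR, TC) to the labeled best superpixel
#' count. Depth is unlimited; node splitting stops once a node holds 4 or
#' fewer samples (realized as a terminal-node size of 5).
#'
#' @param samples Data frame with columns `tar`, `tc`, `k_best` (at least
#'   10 rows).
#' @param seed Integer seed controlling the per-tree bootstraps.
#' @param trees Number of trees (default 5).
#' @return List of class `k_model`: the fitted forest plus training
#'   metadata and the K clipping range.
#' @export
train_k_model <- function(samples, seed = 1L, trees = 5L) {
  stopifnot(all(c("tar", "tc", "k_best") %in% names(samples)))
  if (nrow(samples) < 10L) stop("need at least 10 training samples")
  with_seed(seed, {
    # mtry = 2: with only two predictors, sampling one per split discards
    # half the signal; both descriptors enter every split candidate set
    forest <- randomForest::randomForest(
      x = samples[, c("tar", "tc")], y = samples$k_best,
      ntree = trees, nodesize = 5L, mtry = 2L)
  })
  structure(list(forest = forest, k_range = c(10L, 450L),
                 training_meta = list(seed = seed, trees = trees,
                                      stopping = "terminal node size 5",
                                      n = nrow(samples))),
            class = "k_model")
}

#' Predict the superpixel count K for a new slice
#'
#' The forest prediction is rounded to the nearest multiple of 10 and
#' clipped to [10, 450], so the output is always a valid grid value.
#'
#' @param model A `k_model`.
#' @param descriptor A `tumor_descriptor`, or a list/data frame with `tar`
#'   and `tc`.
#' @return Integer K.
#' @export
predict_k <- function(model, descriptor) {
  stopifnot(inherits(model, "k_model"))
  newdata <- data.frame(tar = descriptor$tar, tc = descriptor$tc)
  raw <- predict_k_raw(model, newdata)
  k <- as.integer(floor(raw / 10 + 0.5) * 10)
  pmin(pmax(k, model$k_range[1]), model$k_range[2])
}

predict_k_raw <- function(model, newdata) {
  if (!is.null(model$forest)) {
    as.numeric(predict(model$forest, newdata = newdata))
  } else {
    predict_forest_json(model$trees, newdata)
  }
}

#' Coefficient of determination between labeled and predicted K
#'
#' `R^2 = 1 - sum((k_best - k_predict)^2) / sum((k_best - mean(k_best))^2)`.
#'
#' @param k_best Labeled values.
#' @param k_predict Predicted values (same length).
#' @return Scalar; 1 for perfect prediction, 0 for the mean-only model.
#' @export
r_square <- function(k_best, k_predict) {
  stopifnot(length(k_best) == length(k_predict), length(k_best) > 0)
  denom <- sum((k_best - mean(k_best))^2)
  if (denom == 0) stop("k_best values are all identical")
  1 - sum((k_best - k_predict)^2) / denom
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
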