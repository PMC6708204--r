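#' Specification of a synthetic head phantom
#'
#' Phantoms emulate a single T2-weighted axial slice: a bilaterally
#' symmetric elliptical head on a black background (background intensity
#' 0, i.e. below 5), smooth mirror-symmetric internal tissue structure
#' (bands and ventricle-like dark ellipses) on a 12-bit intensity scale
#' (tissue roughly 200-1100), and optionally a bright irregular tumor blob
#' confined to one hemisphere with intensity `tissue + tumor_contrast`
#' (T2 tumors and edema appear bright). Additive Gaussian noise is drawn
#' independently per pixel inside the head.
#'
#' @param seed Integer seed; every phantom is deterministic per seed.
#' @param size Slice side in pixels; must be divisible by 16 (default 240,
#'   the grid geometry of the hemispheric similarity map).
#' @param tumor_radius Mean tumor radius in pixels (default 24).
#' @param tumor_contrast Intensity units added above surrounding tissue
#'   (default 600; high contrast, as for bright T2 edema).
#' @param irregularity Tumor boundary perturbation amplitude in [0, 1]
#'   (default 0.3); larger values give a more complex boundary and so a
#'   larger TC by construction.
#' @param noise_sd Noise standard deviation in intensity units
#'   (default 15).
#' @param hemisphere `"left"` or `"right"` (default `"left"`).
#' @return Validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, size = 240L, tumor_radius = 24,
                         tumor_contrast = 600, irregularity = 0.3,
                         noise_sd = 15, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (size %% 16L != 0L) stop("size must be divisible by 16")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (irregularity < 0 || irregularity > 1)
    stop("irregularity must be in [0, 1]")
  if (tumor_radius * (1 + irregularity) > 0.145 * size)
    stop("tumor does not fit inside its hemisphere")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 tumor_radius = tumor_radius, tumor_contrast = tumor_contrast,
                 irregularity = irregularity, noise_sd = noise_sd,
                 hemisphere = hemisphere),
            class = "phantom_spec")
}

# deterministic symmetric anatomy: head mask and noiseless tissue image
phantom_anatomy <- function(size) {
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size) - ctr        # dy
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr  # dx
  ax <- abs(cc)  # symmetric in the midline by construction
  head <- (ax / (0.36 * size))^2 + (rr / (0.42 * size))^2 <= 1
  # smooth symmetric tissue bands: length scales ~ one grid cell so every
  # 15x15 cell has intensity structure well above the noise floor
  tissue <- 650 + 180 * sin(rr / (size / 14)) + 140 * cos(ax / (size / 16)) +
    120 * cos(sqrt(ax^2 + rr^2) / (size / 18))
  # bright skull rim
  rim <- (ax / (0.36 * size))^2 + (rr / (0.42 * size))^2
  tissue[rim > 0.88 & rim <= 1] <- 1000
  # dark ventricle-like ellipses, one mirrored pair
  vent <- ((ax - 0.075 * size) / (0.05 * size))^2 +
    ((rr + 0.05 * size) / (0.12 * size))^2 <= 1
  tissue[vent] <- 280
  img <- matrix(0, size, size)
  img[head] <- tissue[head]
  list(image = img, head = head)
}

#' Generate a symmetric (tumor-free) head phantom
#'
#' With `noise_sd = 0` the image equals its own horizontal mirror exactly;
#' the background is identically 0 (< 5).
#'
#' @param spec A `phantom_spec`.
#' @return Numeric intensity matrix.
#' @export
generate_symmetric_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  anat <- phantom_anatomy(spec$size)
  img <- anat$image
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(rnorm(spec$size^2, sd = spec$noise_sd),
                              spec$size, spec$size))
    img[anat$head] <- pmax(img[anat$head] + noise[anat$head], 5)
  }
  img
}

#' Generate a tumor phantom and its exact ground-truth mask
#'
#' The symmetric phantom plus a bright blob — a disk whose radius is
#' modulated by a low-order random harmonic series scaled by
#' `irregularity` — placed in the requested hemisphere. Tumor pixels take
#' the homogeneous intensity `tissue level + tumor_contrast` before noise
#' (the blob replaces the local anatomy, the way edema overwrites normal
#' structure on T2). The blob never crosses the midline (error if the
#' spec would make it). The tumor shape is drawn from a seed stream
#' separate from the noise stream, so with `tumor_contrast = 0` the image
#' is identical to the symmetric phantom while the mask is still
#' returned.
#'
#' @param spec A `phantom_spec`.
#' @return List: `image` (intensity matrix), `mask` (binary ground truth).
#' @export
generate_tumor_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$size
  anat <- phantom_anatomy(size)

  shape <- with_seed(spec$seed + 7919L, {
    list(row_c = (0.5 + runif(1, -0.08, 0.08)) * size,
         col_c = (0.32 + runif(1, -0.02, 0.02)) * size,
         a = rnorm(4) / (2:5), b = rnorm(4) / (2:5))
  })
  if (spec$hemisphere == "right") shape$col_c <- size - shape$col_c + 1

  rr <- matrix(seq_len(size), size, size) - shape$row_c
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - shape$col_c
  theta <- atan2(rr, cc)
  s <- matrix(0, size, size)
  for (k in 1:4)
    s <- s + shape$a[k] * cos((k + 1) * theta) + shape$b[k] * sin((k + 1) * theta)
  smax <- sum(sqrt(shape$a^2 + shape$b^2))
  s <- s / max(smax, 1e-9)  # |s| <= 1
  radius <- spec$tumor_radius * (1 + spec$irregularity * s)
  mask <- sqrt(rr^2 + cc^2) <= radius

  half <- size %/% 2L
  cols_hit <- which(apply(mask, 2, any))
  crossing <- if (spec$hemisphere == "left") any(cols_hit > half)
  else any(cols_hit <= half)
  if (crossing) stop("tumor would cross the midline")

  img <- anat$image
  # edema replaces the local anatomy: a homogeneous blob at the nominal
  # tissue level plus the contrast (zero contrast leaves the anatomy
  # untouched so the image degenerates to the symmetric phantom)
  if (spec$tumor_contrast > 0) img[mask] <- 650 + spec$tumor_contrast
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(rnorm(size^2, sd = spec$noise_sd), size, size))
    img[anat$head] <- pmax(img[anat$head] + noise[anat$head], 5)
  }
  list(image = img, mask = matrix(as.integer(mask), size, size))
}

#' Generate a synthetic (TAR, TC) -> K training set
#'
#' Samples `TAR ~ U(0.01, 0.3)`, `TC ~ U(0.1, 1.0)` and
#' `k = clip(round10(600 TAR + 120 TC + eps), 10, 450)` with
#' `eps ~ N(0, 10^2)`: a known monotone descriptor-to-K mapping plus
#' noise, used to verify that the forest recovers the mapping (held-out
#' R-squared).
#'
#' @param n Number of samples (>= 10).
#' @param seed Integer seed.
#' @return Data frame with columns `tar`, `tc`, `k_best` (multiples of 10
#'   in [10, 450]).
#' @export
generate_k_dataset <- function(n, seed = 1L) {
  if (n < 10L) stop("n must be >= 10")
  with_seed(seed, {
    tar <- runif(n, 0.01, 0.3)
    tc <- runif(n, 0.1, 1.0)
    eps <- rnorm(n, sd = 10)
    k <- floor((600 * tar + 120 * tc + eps) / 10 + 0.5) * 10
    data.frame(tar = tar, tc = tc,
               k_best = as.integer(pmin(pmax(k, 10), 450)))
  })
}

#' Write a set of phantom fixtures to disk
#'
#' Generates `n` tumor phantoms with seeded variation in tumor radius and
#' boundary irregularity and writes paired 16-bit PNGs plus a manifest
#' TSV.
#'
#' @param out_dir Output directory (created if missing).
#' @param n Number of phantoms (default 20).
#' @param seed Integer seed.
#' @param contrast,noise_sd Phantom intensity parameters passed through to
#'   [phantom_spec()].
#' @return Invisibly, the manifest data frame (`sample`, `slice`, `mask`,
#'   `tumor_radius`, `irregularity`, plus the shared parameters).
#' @export
make_fixtures <- function(out_dir, n = 20L, seed = 1L, contrast = 600,
                          noise_sd = 15) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- with_seed(seed, data.frame(
    sample = seq_len(n),
    seed = seed * 1000L + seq_len(n),
    tumor_radius = runif(n, 12, 24),
    irregularity = runif(n, 0.1, 0.4)))
  rows <- lapply(seq_len(n), function(i) {
    sp <- phantom_spec(seed = pars$seed[i], tumor_radius = pars$tumor_radius[i],
                       irregularity = pars$irregularity[i],
                       tumor_contrast = contrast, noise_sd = noise_sd)
    ph <- generate_tumor_phantom(sp)
    slice_path <- file.path(out_dir, sprintf("slice_%03d.tif", i))
    mask_path <- file.path(out_dir, sprintf("mask_%03d.png", i))
    write_slice(round(ph$image), slice_path)
    write_mask(ph$mask, mask_path)
    data.frame(sample = i, slice = slice_path, mask = mask_path,
               tumor_radius = pars$tumor_radius[i],
               irregularity = pars$irregularity[i],
               tumor_contrast = contrast, noise_sd = noise_sd)
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
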