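#' Read a 2D slice from a NIfTI volume or a PNG/TIFF image
#'
#' Intensities are never rescaled at read time: the 12-bit intensity scale of
#' T2-weighted MRI matters downstream (the background threshold of 5 and the
#' gray-level quantization both assume raw units). 16-bit PNG files are
#' decoded back to integer intensities; TIFF files are read as stored.
#'
#' @param path Path to a `.nii`/`.nii.gz` volume or a `.png`/`.tif`/`.tiff`
#'   2D image.
#' @param slice_index For 3D volumes, the 0-based index of the slice to
#'   extract along the third axis (`slice_index = 77` returns the 78th
#'   slice). Ignored for 2D inputs.
#' @return A numeric matrix (rows x cols) of non-negative intensities.
#' @export
read_slice <- function(path, slice_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    vol <- as.array(RNifti::readNifti(path))
    if (length(dim(vol)) == 2L) {
      img <- vol
    } else if (length(dim(vol)) == 3L) {
      if (is.null(slice_index)) stop("slice_index required for a 3D volume")
      if (slice_index < 0L || slice_index >= dim(vol)[3])
        stop("slice_index out of range [0, ", dim(vol)[3] - 1L, "]")
      img <- vol[, , slice_index + 1L]
    } else stop("unsupported volume dimensionality: ", length(dim(vol)))
  } else if (ext == ".png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
    if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
    img <- round(raw * (2^depth - 1))
  } else if (ext %in% c(".tif", ".tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
    img <- raw
  } else stop("unsupported image format: ", path)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  assert_slice(img)
  img
}

#' Write a 2D slice losslessly
#'
#' 12-bit (and up to 16-bit) integer intensities round-trip exactly
#' through [read_slice()] when written as 16-bit TIFF (`.tif`/`.tiff`).
#' PNG output is 8-bit and therefore only accepted for intensities up to
#' 255.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param path Output path ending in `.tif`/`.tiff` (16-bit) or `.png`
#'   (8-bit).
#' @return Invisibly, `path`.
#' @export
write_slice <- function(image, path) {
  assert_slice(image)
  ext <- tolower(sub("^.*(\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".tif", ".tiff")) {
    if (max(image) > 65535) stop("intensities exceed the 16-bit range")
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  } else if (ext == ".png") {
    if (max(image) > 255)
      stop("PNG output is 8-bit; use a .tif path for 12-bit intensities")
    png::writePNG(image / 255, path)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

#' Write a binary mask as a lossless PNG
#'
#' Binary values survive 8-bit PNG exactly.
#'
#' @param mask Matrix with values in \{0, 1\}.
#' @param path Output path ending in `.png` (or `.tif`/`.tiff`).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  write_slice(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask (any nonzero value maps to 1)
#'
#' @param path Path to a mask written by [write_mask()] or any 2D image.
#' @return An integer matrix with values in \{0, 1\}.
#' @export
read_mask <- function(path) {
  img <- read_slice(path)
  m <- matrix(as.integer(img != 0), nrow(img), ncol(img))
  m
}

#' Pick the median-tumor slice of a volume
#'
#' Returns the 0-based index of the slice at the median position of the
#' tumor voxels along the slice axis: the first index at which the
#' cumulative per-slice tumor voxel count reaches half the total (ties to
#' the lower index). This is the slice used as the representative 2D image
#' of a 3D ground-truth volume.
#'
#' @param volume 3D intensity array (unused except for dimension checking;
#'   may be `NULL`).
#' @param gt_volume 3D binary array of tumor voxels.
#' @return Integer 0-based slice index.
#' @export
select_median_tumor_slice <- function(volume, gt_volume) {
  if (!is.null(volume) && !identical(dim(volume), dim(gt_volume)))
    stop("volume and gt_volume dimensions differ")
  counts <- apply(gt_volume != 0, 3, sum)
  total <- sum(counts)
  if (total == 0) stop("ground truth contains no tumor voxels")
  which(cumsum(counts) >= total / 2)[1L] - 1L
}

# internal validators -------------------------------------------------------

assert_slice <- function(image, min_dim = 32L) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop("slice must be at least ", min_dim, "x", min_dim)
  if (any(!is.finite(image))) stop("slice contains non-finite values")
  if (any(image < 0)) stop("slice contains negative intensities")
  invisible(image)
}

assert_mask <- function(mask, image = NULL) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) stop("mask values must be strictly binary")
  if (!is.null(image) && !identical(dim(mask), dim(image)))
    stop("mask dimensions differ from its slice")
  invisible(mask)
}
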