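#' SLIC clustering distance between a pixel and a cluster center
#'
#' The joint gray/spatial distance used by SLIC k-means clustering:
#' \deqn{D = \sqrt{d_c^2 + (d_s / S)^2 C^2}}
#' where \eqn{d_c = |I_i - I_j|} is the gray-value distance and \eqn{d_s}
#' the Euclidean pixel distance. The grid interval \eqn{S = \sqrt{N/K}}
#' limits the range of local clustering; the compactness \eqn{C} balances
#' gray against spatial distance (large C: smooth, regular superpixels;
#' small C: boundaries hug image edges).
#'
#' @param pixel_gray Pixel intensity.
#' @param pixel_pos Numeric `(row, col)` of the pixel.
#' @param center_gray Center intensity.
#' @param center_pos Numeric `(row, col)` of the center.
#' @param S Grid interval in pixels (> 0).
#' @param C Compactness (> 0).
#' @return Non-negative scalar distance; zero iff gray and position coincide.
#' @export
slic_distance <- function(pixel_gray, pixel_pos, center_gray, center_pos, S, C) {
  if (S <= 0) stop("S must be positive")
  if (C <= 0) stop("C must be positive")
  d_c <- abs(pixel_gray - center_gray)
  d_s <- sqrt(sum((pixel_pos - center_pos)^2))
  sqrt(d_c^2 + (d_s / S)^2 * C^2)
}

#' Seed SLIC cluster centers on a regular grid
#'
#' Centers are placed on a regular grid with spacing \eqn{S = \sqrt{N/K}}
#' and then moved to the lowest-gradient position within their 3x3
#' neighborhood, so that no seed starts on an image edge. The realized
#' center count is `round(h/S) * round(w/S)`, within about 10% of `K`.
#'
#' @param image Numeric intensity matrix.
#' @param K Requested number of superpixels, `1 <= K <= length(image)`.
#' @return Matrix with one row per center and columns `gray`, `row`, `col`
#'   (1-based), plus attribute `S`.
#' @export
initialize_centers <- function(image, K) {
  assert_slice(image, min_dim = 2L)
  N <- length(image)
  if (K < 1L || K > N) stop("K must be in [1, ", N, "]")
  h <- nrow(image); w <- ncol(image)
  S <- sqrt(N / K)
  ny <- max(1L, round(h / S))
  nx <- max(1L, min(w, round(K / ny)))  # keep ny * nx close to K
  grad <- gradient_magnitude_sq(image)
  centers <- matrix(0, ny * nx, 3,
                    dimnames = list(NULL, c("gray", "row", "col")))
  k <- 1L
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      r0 <- (i - 0.5) * h / ny + 0.5
      c0 <- (j - 0.5) * w / nx + 0.5
      ri <- min(max(1L, as.integer(floor(r0 + 0.5) - 1L) + 1L), h)
      ci <- min(max(1L, as.integer(floor(c0 + 0.5) - 1L) + 1L), w)
      # perturb to the 3x3 arg-min of the gradient magnitude (strict <,
      # row-major scan, so the perturbation is a no-op on flat gradients)
      best <- grad[ri, ci]; br <- ri; bc <- ci
      for (dr in -1:1) for (dc in -1:1) {
        rr <- ri + dr; cc <- ci + dc
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w && grad[rr, cc] < best) {
          best <- grad[rr, cc]; br <- rr; bc <- cc
        }
      }
      centers[k, ] <- c(image[br, bc], br, bc)
      k <- k + 1L
    }
  }
  attr(centers, "S") <- S
  centers
}

# squared gradient magnitude with clamped (edge-replicated) neighbors
gradient_magnitude_sq <- function(image) {
  h <- nrow(image); w <- ncol(image)
  right <- image[, c(2:w, w)]; left <- image[, c(1, 1:(w - 1))]
  down <- image[c(2:h, h), ]; up <- image[c(1, 1:(h - 1)), ]
  (right - left)^2 + (down - up)^2
}

#' Run SLIC superpixel clustering with fixed compactness
#'
#' Iterative assign/update k-means: each pixel is assigned to the nearest
#' center under [slic_distance()] among centers whose 2Sx2S search window
#' covers it; centers then move to the mean gray/position of their members.
#' Connectivity is enforced at the end by absorbing fragments smaller than
#' `(N/K)/4` pixels into their largest adjacent component. Deterministic
#' for fixed inputs.
#'
#' @param image Numeric intensity matrix.
#' @param K Requested number of superpixels.
#' @param C Compactness (> 0).
#' @param iterations Number of assign/update iterations (default 10).
#' @param enforce Enforce 4-connectivity of the final labels (default
#'   `TRUE`; set `FALSE` to inspect raw k-means assignments).
#' @return A `superpixel_map`: list with `labels` (integer matrix, labels
#'   `0..count-1`) and `count`.
#' @export
run_slic <- function(image, K, C, iterations = 10L, enforce = TRUE) {
  assert_slice(image, min_dim = 2L)
  if (C <= 0) stop("C must be positive")
  centers <- initialize_centers(image, K)
  res <- cpp_slic(image, centers, attr(centers, "S"), C, as.integer(iterations),
                  FALSE, 1)
  finalize_superpixels(res$labels, K, length(image), enforce)
}

#' Run SLIC0 (zero-parameter SLIC) superpixel clustering
#'
#' As [run_slic()], but the compactness adapts per superpixel: the first
#' iteration uses `init_C`, and from the second iteration on each center
#' uses the running maximum gray distance observed among its members
#' (floored at 1 intensity unit). Flat regions therefore get compact,
#' regular superpixels while high-variance regions let boundaries follow
#' image edges — no compactness tuning is required.
#'
#' @inheritParams run_slic
#' @param init_C Compactness for the first iteration (default 10).
#' @return A `superpixel_map` (see [run_slic()]).
#' @export
run_slic0 <- function(image, K, iterations = 10L, init_C = 10, enforce = TRUE) {
  assert_slice(image, min_dim = 2L)
  centers <- initialize_centers(image, K)
  res <- cpp_slic(image, centers, attr(centers, "S"), init_C,
                  as.integer(iterations), TRUE, 1)
  finalize_superpixels(res$labels, K, length(image), enforce)
}

#' Enforce 4-connectivity of a superpixel label grid
#'
#' Every connected component smaller than `min_size` pixels is merged into
#' its largest adjacent component; labels are then renumbered `0..count-1`.
#' After this step each label is a single 4-connected component.
#'
#' @param labels Integer label matrix (any values).
#' @param min_size Minimum component size in pixels; the SLIC wrappers use
#'   `(N/K)/4`.
#' @return A `superpixel_map`.
#' @export
enforce_connectivity <- function(labels, min_size = 1) {
  lab <- cpp_enforce_connectivity(labels, min_size)
  superpixel_map(lab)
}

superpixel_map <- function(labels) {
  structure(list(labels = labels, count = max(labels) + 1L),
            class = "superpixel_map")
}

finalize_superpixels <- function(labels, K, N, enforce) {
  if (enforce) {
    enforce_connectivity(labels, min_size = (N / K) / 4)
  } else {
    # renumber to 0..count-1 without merging
    u <- unique(as.vector(labels))
    superpixel_map(matrix(match(labels, sort(u)) - 1L, nrow(labels), ncol(labels)))
  }
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat("superpixel_map:", x$count, "superpixels over a",
      nrow(x$labels), "x", ncol(x$labels), "grid\n")
  invisible(x)
}

#' Serialize a superpixel map to a 16-bit label image plus a JSON sidecar
#'
#' @param sp A `superpixel_map`.
#' @param path Output TIFF path (`.tif`); the sidecar is written at
#'   `<path>.json`.
#' @param meta Named list merged into the sidecar (e.g. `K_requested`,
#'   `C` or `"slic0"`).
#' @return Invisibly, `path`.
#' @export
write_superpixels <- function(sp, path, meta = list()) {
  if (sp$count > 65536) stop("too many labels for 16-bit serialization")
  tiff::writeTIFF(sp$labels / 65535, path, bits.per.sample = 16L)
  sidecar <- c(list(count = sp$count), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a superpixel map written by [write_superpixels()]
#'
#' @param path Label-image path previously written by [write_superpixels()].
#' @return A `superpixel_map` with the sidecar attached as attribute `meta`.
#' @export
read_superpixels <- function(path) {
  lab <- tiff::readTIFF(path, as.is = TRUE)
  sp <- superpixel_map(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) attr(sp, "meta") <- jsonlite::read_json(sidecar)
  sp
}
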