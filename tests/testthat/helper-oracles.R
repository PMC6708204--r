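# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles re-derive results from definitions (explicit
# loops, exhaustive enumeration) and never call the code paths they check.

# Brute-force SLIC: evaluates the joint distance for every pixel-center
# pair inside the 2S window with explicit loops; strict-< tie rule, centers
# scanned in order; center update by column-major sums. Labels are raw
# center indices (0-based).
slic_brute_force <- function(image, K, C, iterations, adaptive = FALSE,
                             init_C = 10, floor_C = 1) {
  centers <- initialize_centers(image, K)
  S <- attr(centers, "S")
  h <- nrow(image); w <- ncol(image)
  Kc <- nrow(centers)
  cg <- centers[, 1]; cr <- centers[, 2]; cc <- centers[, 3]
  comp <- rep(if (adaptive) init_C else C, Kc)
  runmax <- rep(0, Kc)
  lab <- NULL
  for (it in seq_len(iterations)) {
    dist <- matrix(Inf, h, w)
    lab <- matrix(-1L, h, w)
    for (k in seq_len(Kc)) {
      lo_r <- max(1, floor(cr[k] - S)); hi_r <- min(h, ceiling(cr[k] + S))
      lo_c <- max(1, floor(cc[k] - S)); hi_c <- min(w, ceiling(cc[k] + S))
      for (cl in lo_c:hi_c) for (r in lo_r:hi_r) {
        dcol <- abs(image[r, cl] - cg[k])
        ds <- sqrt((r - cr[k])^2 + (cl - cc[k])^2)
        t <- ds / S
        D <- sqrt(dcol^2 + (t * t) * (comp[k] * comp[k]))
        if (D < dist[r, cl]) { dist[r, cl] <- D; lab[r, cl] <- k - 1L }
      }
    }
    for (p in which(lab < 0)) {
      r <- (p - 1) %% h + 1; cl <- (p - 1) %/% h + 1
      best <- Inf; bk <- 0L
      for (k in seq_len(Kc)) {
        ds <- (r - cr[k])^2 + (cl - cc[k])^2
        if (ds < best) { best <- ds; bk <- k - 1L }
      }
      lab[p] <- bk
    }
    if (adaptive) {
      for (k in seq_len(Kc)) {
        members <- lab == k - 1L
        if (any(members)) {
          mx <- max(abs(image[members] - cg[k]))
          if (mx > runmax[k]) runmax[k] <- mx
        }
        comp[k] <- max(floor_C, runmax[k])
      }
    }
    for (k in seq_len(Kc)) {
      members <- which(lab == k - 1L)  # column-major order
      if (length(members)) {
        n <- length(members)
        rows <- (members - 1) %% h + 1
        cols <- (members - 1) %/% h + 1
        cg[k] <- sum(image[members]) / n
        cr[k] <- sum(rows) / n
        cc[k] <- sum(cols) / n
      }
    }
  }
  lab
}

# renumber labels to 0..count-1 by sorted original id (mirrors the
# non-merging relabeling of the package)
renumber <- function(lab) {
  matrix(match(lab, sort(unique(as.vector(lab)))) - 1L, nrow(lab), ncol(lab))
}

# exhaustive all-pairs Hausdorff distance on boundary sets
hausdorff_brute_force <- function(a, b) {
  bnd <- function(m) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(FALSE, h, w)
    for (r in seq_len(h)) for (cl in seq_len(w)) {
      if (!m[r, cl]) next
      nb <- c(if (r > 1) m[r - 1, cl] else FALSE,
              if (r < h) m[r + 1, cl] else FALSE,
              if (cl > 1) m[r, cl - 1] else FALSE,
              if (cl < w) m[r, cl + 1] else FALSE)
      out[r, cl] <- !all(nb)
    }
    out
  }
  pa <- which(bnd(a != 0), arr.ind = TRUE)
  pb <- which(bnd(b != 0), arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  directed <- function(x, y) {
    max(vapply(seq_len(nrow(x)), function(i)
      min(sqrt((x[i, 1] - y[, 1])^2 + (x[i, 2] - y[, 2])^2)), numeric(1)))
  }
  max(directed(pa, pb), directed(pb, pa))
}

# exhaustive symmetric pair enumeration for a co-occurrence matrix
glcm_brute_force <- function(quantized, levels, direction) {
  off <- switch(as.character(direction), "0" = c(0, 1), "45" = c(-1, 1),
                "90" = c(-1, 0), "135" = c(-1, -1))
  h <- nrow(quantized); w <- ncol(quantized)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(h)) for (cl in seq_len(w)) {
    r2 <- r + off[1]; c2 <- cl + off[2]
    if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
    a <- quantized[r, cl]; b <- quantized[r2, c2]
    if (is.na(a) || is.na(b)) next
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
  }
  counts
}

# small deterministic random binary mask
random_mask <- function(h, w, p = 0.3, seed = 1) {
  with_local_seed(seed, matrix(as.integer(runif(h * w) < p), h, w))
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# shared small phantom pair set for pipeline-level tests (radius and
# irregularity ladders mirror the fixture generator)
phantom_pairs <- function(n, seed = 1000L) {
  lapply(seq_len(n), function(i) {
    p <- generate_tumor_phantom(phantom_spec(
      seed = seed + i, tumor_radius = 12 + (i %% 7) * 2,
      irregularity = 0.1 + (i %% 5) * 0.07))
    list(image = p$image, mask = p$mask)
  })
}
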