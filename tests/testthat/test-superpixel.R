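test_that("slic distance matches the hand-evaluated joint metric", {
  # d_c = 3, d_s = 4, S = 2, C = 1 -> sqrt(9 + 4) = sqrt(13)
  d <- slic_distance(3, c(0, 0), 0, c(0, 4), S = 2, C = 1)
  expect_equal(d, sqrt(13))
  expect_equal(slic_distance(5, c(2, 3), 5, c(2, 3), S = 2, C = 1), 0)
  # strictly increasing in C at fixed d_c, d_s
  ds <- vapply(c(0.1, 1, 10, 100), function(C)
    slic_distance(3, c(0, 0), 0, c(0, 4), S = 2, C = C), numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_error(slic_distance(1, c(0, 0), 0, c(1, 1), S = 0, C = 1), "S")
  expect_error(slic_distance(1, c(0, 0), 0, c(1, 1), S = 1, C = -1), "C")
})

test_that("center seeding lands on the grid and dodges gradients", {
  flat <- matrix(5, 20, 20)
  cen <- initialize_centers(flat, 4)
  expect_equal(nrow(cen), 4)
  expect_equal(sort(cen[, "row"]), c(6, 6, 16, 16))  # grid, no perturbation
  expect_equal(sort(cen[, "col"]), c(6, 6, 16, 16))

  one <- initialize_centers(flat, 1)
  expect_equal(unname(one[1, c("row", "col")]), c(11, 11))  # near centroid

  # full seeding oracle: grid positions, then exhaustive 3x3 arg-min of
  # the gradient around each grid seed (first minimum in scan order)
  img <- with_local_seed(3, matrix(runif(400) * 100, 20, 20))
  cen2 <- initialize_centers(img, 9)
  grad <- (img[, c(2:20, 20)] - img[, c(1, 1:19)])^2 +
    (img[c(2:20, 20), ] - img[c(1, 1:19), ])^2
  k <- 1L
  for (i in 1:3) for (j in 1:3) {
    ri <- floor((i - 0.5) * 20 / 3 + 0.5 + 0.5)
    ci <- floor((j - 0.5) * 20 / 3 + 0.5 + 0.5)
    best <- c(ri, ci)
    for (dr in -1:1) for (dc in -1:1) {
      rr <- ri + dr; cc <- ci + dc
      if (rr >= 1 && rr <= 20 && cc >= 1 && cc <= 20 &&
          grad[rr, cc] < grad[best[1], best[2]]) best <- c(rr, cc)
    }
    expect_equal(unname(cen2[k, c("row", "col")]), best)
    expect_equal(unname(cen2[k, "gray"]), img[best[1], best[2]])
    k <- k + 1L
  }
  expect_error(initialize_centers(img, 0), "K")
  expect_error(initialize_centers(img, 401), "K")
})

test_that("realized center count stays within 10% of K", {
  img <- with_local_seed(4, matrix(runif(240 * 240) * 1000, 240, 240))
  for (K in c(10, 50, 100, 230, 450)) {
    n <- nrow(initialize_centers(img, K))
    expect_lte(abs(n - K) / K, 0.10)
  }
})

test_that("run_slic degenerate and two-halves cases", {
  img <- with_local_seed(5, matrix(runif(24 * 24) * 50, 24, 24))
  one <- run_slic(img, K = 1, C = 10)
  expect_equal(one$count, 1)
  expect_true(all(one$labels == 0))

  half <- cbind(matrix(0, 20, 10), matrix(100, 20, 10))
  gt <- cbind(matrix(0L, 20, 10), matrix(1L, 20, 10))
  for (sp in list(run_slic(half, 2, C = 10), run_slic0(half, 2))) {
    expect_equal(sp$count, 2)
    right <- matrix(as.integer(sp$labels == sp$labels[1, 20]), 20, 20)
    expect_equal(dice(right, gt), 1)
  }
})

test_that("per-iteration assignments match the brute-force oracle", {
  set.seed(42)
  for (trial in 1:10) {
    h <- sample(12:24, 1); w <- sample(12:24, 1)
    img <- matrix(runif(h * w) * 200, h, w)
    K <- sample(2:8, 1)
    for (it in c(1, 2, 4)) {
      got <- run_slic(img, K, C = 10, iterations = it, enforce = FALSE)
      oracle <- slic_brute_force(img, K, C = 10, iterations = it)
      expect_identical(got$labels, renumber(oracle))
    }
    got0 <- run_slic0(img, K, iterations = 3, enforce = FALSE)
    oracle0 <- slic_brute_force(img, K, C = NA, iterations = 3,
                                adaptive = TRUE)
    expect_identical(got0$labels, renumber(oracle0))
  }
})

test_that("SLIC0 on a constant image degenerates to grid cells", {
  flat <- matrix(7, 24, 24)
  sp0 <- run_slic0(flat, 4)
  tiny <- run_slic(flat, 4, C = 1e-6)
  expect_equal(sp0$count, 4)
  expect_identical(sp0$labels, tiny$labels)
})

test_that("superpixel maps are deterministic partitions", {
  img <- with_local_seed(6, matrix(runif(40 * 40) * 300, 40, 40))
  a <- run_slic0(img, 12)
  b <- run_slic0(img, 12)
  expect_identical(a$labels, b$labels)
  expect_setequal(unique(as.vector(a$labels)), 0:(a$count - 1))
  expect_equal(length(a$labels), 1600)  # every pixel labeled exactly once
})

test_that("connectivity enforcement absorbs fragments and yields connected labels", {
  # orphan pixel inside a large region
  lab <- matrix(0L, 10, 10); lab[5, 5] <- 1L
  sp <- enforce_connectivity(lab, min_size = 4)
  expect_equal(sp$count, 1)

  # already-connected labeling unchanged up to relabeling
  lab2 <- rbind(matrix(0L, 5, 10), matrix(3L, 5, 10))
  sp2 <- enforce_connectivity(lab2, min_size = 2)
  expect_equal(sp2$count, 2)
  expect_equal(sp2$labels[1, 1], 0L)
  expect_equal(sp2$labels[10, 1], 1L)

  # random label grid: every final label is one 4-connected component
  # (flood-fill oracle)
  lab3 <- with_local_seed(9, matrix(sample(0:3, 144, TRUE), 12, 12))
  sp3 <- enforce_connectivity(lab3, min_size = 3)
  for (l in 0:(sp3$count - 1)) {
    pix <- which(sp3$labels == l)
    seen <- rep(FALSE, length(pix))
    stack <- 1L; seen[1] <- TRUE
    coords <- cbind((pix - 1) %% 12 + 1, (pix - 1) %/% 12 + 1)
    while (length(stack)) {
      i <- stack[1]; stack <- stack[-1]
      nb <- which(abs(coords[, 1] - coords[i, 1]) +
                    abs(coords[, 2] - coords[i, 2]) == 1 & !seen)
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    expect_true(all(seen))
  }
})

test_that("larger compactness smooths superpixel boundaries", {
  img <- with_local_seed(10, matrix(runif(60 * 60) * 100, 60, 60))
  boundary_len <- vapply(c(0.1, 1, 10, 100), function(C) {
    sp <- run_slic(img, 16, C = C, enforce = FALSE)
    (sum(sp$labels[, -60] != sp$labels[, -1]) +
       sum(sp$labels[-60, ] != sp$labels[-1, ])) / sp$count
  }, numeric(1))
  # non-increasing up to a 2% tie tolerance (at negligible C the metric is
  # noise-dominated and flat), with a clear overall drop
  expect_true(all(diff(boundary_len) <= 0.02 * boundary_len[-4]))
  expect_lt(boundary_len[4], 0.5 * boundary_len[1])
})

test_that("superpixel maps serialize to PNG + JSON sidecar and back", {
  img <- with_local_seed(12, matrix(runif(40 * 40) * 300, 40, 40))
  sp <- run_slic0(img, 9)
  path <- withr::local_tempfile(fileext = ".tif")
  write_superpixels(sp, path, meta = list(K_requested = 9, C = "slic0"))
  back <- read_superpixels(path)
  expect_identical(back$labels, sp$labels)
  expect_equal(attr(back, "meta")$K_requested, 9)
})
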