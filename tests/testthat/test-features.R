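test_that("intensity statistics: hand cases and degenerate input", {
  s <- intensity_statistics(c(5, 5, 5))
  expect_equal(unname(s["sd"]), 0)
  expect_equal(unname(s["entropy"]), 0, tolerance = 1e-9)
  expect_equal(unname(s["uniformity"]), 1)
  expect_equal(unname(s["skewness"]), 0)
  expect_equal(unname(s["kurtosis"]), 0)

  s2 <- intensity_statistics(1:4)
  expect_equal(unname(s2[c("mean", "median", "range")]), c(2.5, 2.5, 3))
  expect_equal(unname(s2["energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(s2["rms"]), sqrt(30 / 4))
  expect_equal(unname(s2["minimum"]), 1)

  expect_length(intensity_statistics(rnorm(10)), 17)
  expect_error(intensity_statistics(numeric(0)), "empty")
})

test_that("skewness and kurtosis behave like population moments of a normal", {
  x <- with_local_seed(13, rnorm(20000, mean = 50, sd = 4))
  s <- intensity_statistics(x)
  expect_lt(abs(s[["skewness"]]), 0.08)
  expect_lt(abs(s[["kurtosis"]] - 3), 0.15)
})

test_that("gray quantization is linear min-max binning", {
  img <- matrix(0:63, 8, 8)
  q <- quantize_gray(img, 64)
  expect_identical(q, matrix(0:63, 8, 8))  # identity binning

  flat <- matrix(9, 5, 5)
  expect_true(all(quantize_gray(flat, 8) == 0))

  img2 <- with_local_seed(14, matrix(runif(100, 10, 500), 10, 10))
  for (L in c(8, 16, 32, 64)) {
    q2 <- quantize_gray(img2, L)
    expect_true(all(q2 >= 0 & q2 < L))
    # direct binning arithmetic
    oracle <- pmin(floor((img2 - min(img2)) / (max(img2) - min(img2)) * L),
                   L - 1)
    expect_equal(q2, matrix(as.integer(oracle), 10, 10))
  }
  expect_error(quantize_gray(img2, 1), "levels")
})

test_that("co-occurrence matrices count symmetric in-region pairs", {
  # 1x2 region [0, 1], direction 0: entries (0,1) and (1,0), 0.5 each
  q <- matrix(NA_integer_, 3, 3)
  q[2, 2] <- 0L; q[2, 3] <- 1L
  cm <- cooccurrence_matrix(q, levels = 2, direction = 0)
  expect_equal(cm$prob, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  flat <- matrix(0L, 4, 4)
  cmf <- cooccurrence_matrix(flat, levels = 4, direction = 90)
  expect_equal(cmf$prob[1, 1], 1)
  expect_equal(sum(cmf$prob), 1)

  # no valid pair -> flagged empty, features default to zero
  single <- matrix(NA_integer_, 3, 3); single[2, 2] <- 1L
  cme <- cooccurrence_matrix(single, levels = 2, direction = 0)
  expect_true(cme$empty)
  expect_equal(unname(haralick_features(cme)), rep(0, 13))
})

test_that("co-occurrence counts equal brute-force pair enumeration", {
  for (seed in 1:4) {
    q <- with_local_seed(seed, {
      m <- matrix(sample(0:7, 64, TRUE), 8, 8)
      m[sample(64, 12)] <- NA  # ragged region
      m
    })
    for (d in c(0, 45, 90, 135)) {
      got <- cooccurrence_matrix(q, levels = 8, direction = d)
      expect_equal(got$counts, glcm_brute_force(q, 8, d))
    }
  }
})

test_that("Haralick features: deterministic and uniform matrices by hand", {
  p1 <- matrix(0, 2, 2); p1[1, 1] <- 1  # single diagonal entry
  h1 <- haralick_features(p1)
  expect_equal(unname(h1["asm"]), 1)
  expect_equal(unname(h1["entropy"]), 0, tolerance = 1e-9)
  expect_equal(unname(h1["contrast"]), 0)

  pu <- matrix(0.25, 2, 2)  # uniform 2x2
  hu <- haralick_features(pu)
  expect_equal(unname(hu["asm"]), 0.25)
  expect_equal(unname(hu["entropy"]), 2, tolerance = 1e-6)  # bits
  # hand values for the uniform 2x2 matrix
  expect_equal(unname(hu["contrast"]), 0.5)       # |i-j|=1 mass 0.5
  expect_equal(unname(hu["correlation"]), 0)      # independent marginals
  expect_equal(unname(hu["idm"]), 0.5 + 0.25)     # 0.5*1 + 0.5/2
  expect_equal(unname(hu["sum_average"]), 1)      # E[i+j], levels 0..1
})

test_that("Haralick entropy is maximal for the uniform matrix", {
  for (L in c(2, 4)) {
    uniform <- matrix(1 / L^2, L, L)
    hu <- haralick_features(uniform)[["entropy"]]
    for (seed in 1:5) {
      p <- with_local_seed(seed * 10 + L, {
        m <- matrix(runif(L * L), L, L)
        m <- (m + t(m)) / 2
        m / sum(m)
      })
      expect_lte(haralick_features(p)[["entropy"]], hu + 1e-9)
    }
  }
})

test_that("Haralick bounds hold on random matrices", {
  for (seed in 1:5) {
    p <- with_local_seed(seed, { m <- matrix(runif(64), 8, 8); m / sum(m) })
    h <- haralick_features(p)
    expect_gte(h[["contrast"]], 0)
    expect_gt(h[["asm"]], 0)
    expect_lte(h[["asm"]], 1)
    expect_true(all(is.finite(h)))
  }
})

test_that("Roberts map matches direct 2x2 kernel convolution", {
  expect_true(all(roberts_gradient_map(matrix(7, 6, 6)) == 0))

  img <- with_local_seed(15, matrix(runif(25) * 10, 5, 5))
  got <- roberts_gradient_map(img)
  for (r in 1:5) for (cl in 1:5) {
    rp <- min(r + 1, 5); cp <- min(cl + 1, 5)  # edge replication
    g1 <- img[r, cl] - img[rp, cp]
    g2 <- img[r, cp] - img[rp, cl]
    expect_equal(got[r, cl], sqrt(g1^2 + g2^2))
  }

  # step edge: response confined to the edge support
  step <- cbind(matrix(0, 6, 3), matrix(10, 6, 3))
  rg <- roberts_gradient_map(step)
  expect_true(all(rg[, c(1, 2, 5, 6)] == 0))
  expect_true(all(rg[, 3] > 0))
})

test_that("Prewitt map matches direct 3x3 convolution and ramp response", {
  expect_true(all(prewitt_curvature_map(matrix(3, 6, 6)) == 0))

  ramp <- matrix(seq_len(6), 6, 6)  # vertical ramp, slope 1 per row
  pm <- prewitt_curvature_map(ramp)
  expect_true(all(pm[2:5, ] == 6))  # interior kernel sum

  img <- with_local_seed(16, matrix(runif(25) * 10, 5, 5))
  got <- prewitt_curvature_map(img)
  at <- function(r, cl) img[min(max(r, 1), 5), min(max(cl, 1), 5)]
  for (r in 1:5) for (cl in 1:5) {
    px <- py <- 0
    for (d in -1:1) {
      px <- px + at(r + d, cl + 1) - at(r + d, cl - 1)
      py <- py + at(r + 1, cl + d) - at(r - 1, cl + d)
    }
    expect_equal(got[r, cl], sqrt(px^2 + py^2))
  }
})

test_that("curvature map: ramps and flats are zero, oracle on a quadratic", {
  ramp <- matrix(seq_len(8), 8, 8) * 3
  expect_true(all(curvature_map(ramp) == 0))  # second derivatives vanish
  expect_true(all(curvature_map(matrix(5, 8, 8)) == 0))  # degenerate gradient

  # smooth radial quadratic: finite-difference oracle per pixel
  rr <- matrix(1:9, 9, 9); cc <- t(rr)
  img <- (rr - 5)^2 + (cc - 5)^2
  got <- curvature_map(img)
  at <- function(r, cl) img[min(max(r, 1), 9), min(max(cl, 1), 9)]
  for (r in 2:8) for (cl in 2:8) {
    fx <- (at(r, cl + 1) - at(r, cl - 1)) / 2
    fy <- (at(r + 1, cl) - at(r - 1, cl)) / 2
    fxx <- at(r, cl + 1) - 2 * at(r, cl) + at(r, cl - 1)
    fyy <- at(r + 1, cl) - 2 * at(r, cl) + at(r - 1, cl)
    g2 <- fx^2 + fy^2
    want <- if (g2 < 1e-8) 0 else
      (fxx * fy^2 + fyy * fx^2 - 2 * fxx * fx * fy) / g2^1.5
    expect_equal(got[r, cl], want)
  }
  expect_equal(curvature_feature(img, img > 0), mean(got[img > 0]))
})
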