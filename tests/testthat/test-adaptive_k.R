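test_that("midline alignment recovers synthetic shifts and rotations", {
  ph <- generate_tumor_phantom(phantom_spec(seed = 3))$image

  al0 <- align_midline(generate_symmetric_phantom(phantom_spec(seed = 3,
                                                               noise_sd = 0)))
  expect_equal(al0$shift, 0)
  expect_equal(al0$rotation, 0)

  al_s <- align_midline(shift_horizontal(ph, 6))
  expect_lte(abs(al_s$shift - (-6)), 1)

  al_r <- align_midline(rotate_image(ph, 4))
  expect_lte(abs(al_r$rotation - (-4)), 1)

  expect_error(align_midline(matrix(0, 240, 240)), "all-background")
})

test_that("grid similarity is Pearson correlation on mirrored cell pairs", {
  img <- with_local_seed(21, matrix(runif(240 * 240) * 1000, 240, 240))
  sym <- (img + img[, 240:1]) / 2  # exactly mirror-symmetric
  sim <- grid_similarity(sym)
  expect_equal(dim(sim$r_values), c(16, 16))
  expect_equal(length(sim$r_values), 256)
  expect_true(all(abs(sim$r_values - 1) < 1e-12))

  # anticorrelated mirror: B = c - A
  anti <- img
  anti[, 121:240] <- (2000 - img[, 120:1])
  sim2 <- grid_similarity(anti)
  expect_true(all(abs(sim2$r_values + 1) < 1e-12))

  # random cells: r matches a direct covariance/variance computation
  sim3 <- grid_similarity(img)
  i <- 5; j <- 3
  a <- img[61:75, 31:45]
  b <- img[61:75, 210:196]
  oracle <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(sim3$r_values[i, j], oracle, tolerance = 1e-12)

  # zero-variance cells are flagged and treated as symmetric
  flat <- matrix(0, 240, 240); flat[100:140, 100:140] <- 800
  sim4 <- grid_similarity(flat)
  expect_true(any(sim4$undefined))
  expect_true(all(sim4$r_values[sim4$undefined] == 1))
})

test_that("block flagging counts left-hemisphere cells below threshold", {
  sim <- structure(list(r_values = matrix(1, 16, 16),
                        undefined = matrix(FALSE, 16, 16), cell_size = 15L),
                   class = "grid_similarity")
  fl <- flag_suspected_blocks(sim)
  expect_equal(fl$n_blocks, 0)
  expect_equal(sum(fl$mask), 0)

  sim$r_values[c(3, 20, 100)] <- 0.5  # three left-hemisphere cells
  fl2 <- flag_suspected_blocks(sim)
  expect_equal(fl2$n_blocks, 3)
  expect_equal(sum(fl2$mask), 3 * 225)

  # threshold is strict: r == threshold is not flagged
  sim$r_values[] <- 1; sim$r_values[4] <- 0.81
  expect_equal(flag_suspected_blocks(sim, 0.81)$n_blocks, 0)
})

test_that("flagged cells cover a left-hemisphere tumor blob", {
  ph <- generate_tumor_phantom(phantom_spec(seed = 6, tumor_radius = 22,
                                            irregularity = 0.1))
  desc <- tumor_descriptor(ph$image)
  # cells overlapping the blob by >= 50% must be flagged
  fl_mask <- desc$suspected
  for (i in 1:16) for (j in 1:8) {
    rows <- ((i - 1) * 15 + 1):(i * 15); cols <- ((j - 1) * 15 + 1):(j * 15)
    if (mean(ph$mask[rows, cols]) >= 0.5)
      expect_true(all(fl_mask[rows, cols] == 1))
  }
})

test_that("TAR is the flagged-cell fraction of 256", {
  expect_equal(compute_tar(0), 0)
  expect_equal(compute_tar(256), 1)
  expect_equal(compute_tar(64), 0.25)
  expect_error(compute_tar(-1), "n_blocks")
  expect_error(compute_tar(300), "n_blocks")
})

test_that("TC is the boundary-to-area pixel ratio", {
  expect_equal(compute_tc(matrix(0L, 20, 20)), 0)
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L  # 10x10 filled square
  expect_equal(compute_tc(sq), 36 / 100)
  px <- matrix(0L, 20, 20); px[3, 3] <- 1L
  expect_equal(compute_tc(px), 1)
})

test_that("TC agrees with exhaustive pixel classification on random masks", {
  for (seed in 1:5) {
    m <- random_mask(18, 22, p = 0.4, seed = seed)
    area <- sum(m)
    edge <- 0
    for (r in 1:18) for (cl in 1:22) {
      if (!m[r, cl]) next
      outside <- (r == 1 || !m[r - 1, cl]) || (r == 18 || !m[r + 1, cl]) ||
        (cl == 1 || !m[r, cl - 1]) || (cl == 22 || !m[r, cl + 1])
      edge <- edge + outside
    }
    expect_equal(compute_tc(m), edge / area)
  }
})

test_that("best-K labeling returns a plateau median that achieves near-max Dice", {
  half <- cbind(matrix(0, 48, 24), matrix(100, 48, 24))
  gt <- cbind(matrix(0L, 48, 24), matrix(1L, 48, 24))
  grid <- seq(10, 90, 10)
  k <- label_best_k(half, gt, k_grid = grid)
  d <- attr(k, "dice")
  expect_gte(d[as.character(k)], max(d) - 0.01)
  # Dice approximately 1 over the full grid -> plateau median is the
  # middle grid value
  expect_true(all(d >= 0.99))
  expect_equal(as.integer(k), 50L)

  ph <- generate_tumor_phantom(phantom_spec(seed = 4))
  k2 <- label_best_k(ph$image, ph$mask, k_grid = seq(20, 200, 20))
  d2 <- attr(k2, "dice")
  expect_gte(d2[as.character(k2)], max(d2) - 0.01)

  expect_error(label_best_k(half, gt * 0L), "empty")
})

test_that("the K forest reproduces a constant target and bounds predictions", {
  samples <- with_local_seed(31, data.frame(
    tar = runif(20, 0.01, 0.3), tc = runif(20, 0.1, 1), k_best = 100L))
  m <- suppressWarnings(train_k_model(samples, seed = 5))
  for (tar in c(0.01, 0.15, 0.3))
    expect_equal(predict_k(m, list(tar = tar, tc = 0.5)), 100L)

  samp2 <- generate_k_dataset(50, seed = 2)
  m2 <- train_k_model(samp2, seed = 5)
  preds <- as.numeric(predict(m2$forest,
                              newdata = samp2[1:10, c("tar", "tc")]))
  expect_true(all(preds >= min(samp2$k_best) & preds <= max(samp2$k_best)))

  expect_error(train_k_model(samples[1:5, ], seed = 1), "at least 10")
})

test_that("K predictions are grid values: rounded to 10s and clipped", {
  samples <- generate_k_dataset(40, seed = 3)
  m <- train_k_model(samples, seed = 1)
  descs <- with_local_seed(32, data.frame(tar = runif(20, 0, 0.5),
                                          tc = runif(20, 0, 1.5)))
  for (i in 1:20) {
    k <- predict_k(m, descs[i, ])
    expect_true(k %% 10 == 0 && k >= 10 && k <= 450)
  }
  # constant low targets exercise the clip
  lo <- suppressWarnings(train_k_model(with_local_seed(33, data.frame(
    tar = runif(12), tc = runif(12), k_best = 10L)), seed = 1))
  expect_equal(predict_k(lo, list(tar = 0.5, tc = 0.5)), 10L)
})

test_that("r_square matches the direct formula", {
  expect_equal(r_square(c(10, 20, 30), c(10, 20, 30)), 1)
  expect_equal(r_square(c(10, 20, 30), rep(20, 3)), 0)
  kb <- c(10, 20, 30); kp <- c(12, 18, 31)
  expect_equal(r_square(kb, kp),
               1 - (4 + 4 + 1) / sum((kb - 20)^2))
  expect_error(r_square(c(5, 5), c(4, 6)), "identical")
})

test_that("the forest recovers a synthetic monotone descriptor-to-K mapping", {
  data <- generate_k_dataset(200, seed = 7)
  train <- data[1:160, ]; test <- data[161:200, ]
  model <- train_k_model(train, seed = 7)
  preds <- predict(model$forest, newdata = test[, c("tar", "tc")])
  expect_gte(r_square(test$k_best, preds), 0.9)
})

test_that("K model JSON round-trip preserves predictions", {
  data <- generate_k_dataset(60, seed = 9)
  model <- train_k_model(data, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  save_k_model(model, path)
  loaded <- load_k_model(path)
  for (i in seq(1, 60, 7)) {
    expect_equal(predict_k(loaded, data[i, ]), predict_k(model, data[i, ]))
  }
})
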