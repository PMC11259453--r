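test_that("z-score input statistics standardize the training set", {
  set.seed(4)
  M <- matrix(rnorm(50 * 8, mean = rep(c(-10, 40), each = 4 * 50)), 50, 8)
  st <- fit_input_stats(M)
  Z <- apply_input_stats(M, st)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
  # permutation invariance
  st2 <- fit_input_stats(M[sample(50), ])
  expect_equal(st2$center, st$center)
  expect_equal(st2$scale, st$scale)
  expect_error(fit_input_stats(M[1, , drop = FALSE]), "2 training examples")
})

test_that("dead channels are floored with a warning and transform to zero", {
  M <- cbind(matrix(rnorm(20), 10, 2), rep(3.14, 10))
  expect_warning(st <- fit_input_stats(M), "constant")
  Z <- apply_input_stats(M, st)
  expect_true(all(Z[, 3] == 0))
})

test_that("min-max target normalization round-trips exactly", {
  set.seed(8)
  y <- array(runif(16 * 16 * 8 * 2 * 5, 0.001, 0.02), c(16, 16, 8, 2, 5))
  y[, , , 2, ] <- y[, , , 2, ] * 100
  st <- fit_target_stats(y)
  yn <- normalize_targets(y, st)
  expect_equal(min(yn[, , , 1, ]), 0)
  expect_equal(max(yn[, , , 1, ]), 1)
  expect_equal(min(yn[, , , 2, ]), 0)
  expect_equal(max(yn[, , , 2, ]), 1)
  back <- denormalize_predictions(yn, st)
  expect_equal(back, y, tolerance = 1e-12)
})

test_that("a midpoint value maps to one half under two-point extremes", {
  y <- array(0, c(1, 1, 1, 2, 2))
  y[1, 1, 1, 1, ] <- c(0.004, 0.012)
  y[1, 1, 1, 2, ] <- c(0.5, 1.5)
  st <- fit_target_stats(y)
  probe <- array(c(0.008, 1.0), c(1, 1, 1, 2, 1))
  expect_equal(as.vector(normalize_targets(probe, st)), c(0.5, 0.5))
})

test_that("target preparation downsamples to the 16x16x8x2 tensor", {
  g <- volume_geometry()
  vol <- list(mua = array(0.007, g$fine_dim), musp = array(1.1, g$fine_dim))
  tgt <- prepare_target(vol, g)
  expect_equal(dim(tgt), c(16L, 16L, 8L, 2L))
  # interpolation reproduces constants
  expect_true(all(abs(tgt[, , , 1] - 0.007) < 1e-12))
  expect_true(all(abs(tgt[, , , 2] - 1.1) < 1e-12))
  # a linear ramp along x is reproduced at the coarse voxel centers
  fx <- (seq_len(g$fine_dim[1]) - 0.5) * g$fine_spacing_mm
  ramp <- array(rep(0.001 + 1e-4 * fx, g$fine_dim[2] * g$fine_dim[3]),
                g$fine_dim)
  vol2 <- list(mua = ramp, musp = array(1, g$fine_dim))
  tgt2 <- prepare_target(vol2, g)
  tg <- coarse_target_grid(g)
  cx <- grid_centers(tg)$x
  expect_equal(tgt2[, 8, 4, 1], 0.001 + 1e-4 * cx, tolerance = 1e-6)
  # the trilinear alternative agrees on smooth fields
  tgt3 <- prepare_target(vol2, g, method = "trilinear")
  expect_equal(tgt3[, 8, 4, 1], 0.001 + 1e-4 * cx, tolerance = 1e-6)
})

test_that("min-max input scaling is available behind the method switch", {
  set.seed(9)
  M <- matrix(rnorm(30 * 4), 30, 4)
  st <- fit_input_stats(M, method = "minmax")
  Z <- apply_input_stats(M, st)
  expect_equal(unname(apply(Z, 2, min)), rep(0, 4))
  expect_equal(unname(apply(Z, 2, max)), rep(1, 4))
})
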