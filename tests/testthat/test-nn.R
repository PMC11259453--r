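tiny_net_config <- function() {
  fdunet_config(input_dim = 6, output_dim = c(4, 4, 2),
                n_encoder_decoder_conv_layers = 2, filters_per_layer = 3,
                unet_filters = c(2, 3), dropout_rate = 0)
}

test_that("forward pass maps measurement vectors to two-channel volumes", {
  cfg <- tiny_net_config()
  p <- build_fdu_net(cfg, seed = 1)
  X <- matrix(rnorm(3 * 6), 3, 6)
  E <- fddot:::fdnet_forward(p, X, cfg)$out
  expect_equal(dim(E), c(4L, 4L, 2L, 2L, 3L))
  out <- fddot:::unet_forward(p$un, E)$out
  expect_equal(dim(out), c(4L, 4L, 2L, 2L, 3L))
  # zero weights produce identically zero output
  p0 <- rapply(p, function(x) x * 0, how = "replace")
  expect_true(all(fddot:::fdnet_forward(p0, X, cfg)$out == 0))
  # seeded initialization is reproducible
  expect_identical(build_fdu_net(cfg, seed = 5), build_fdu_net(cfg, seed = 5))
  expect_false(identical(build_fdu_net(cfg, seed = 5),
                         build_fdu_net(cfg, seed = 6)))
})

test_that("ROI loss matches its hand-computed definition", {
  # 4-voxel toy: 2 ROI voxels with squared errors 0.01, 0.04; 2 background
  # with 0.09, 0.16 (both channels identical so the means are unchanged)
  pred <- array(0, c(2, 2, 1, 2, 1))
  target <- array(0, c(2, 2, 1, 2, 1))
  err <- sqrt(c(0.01, 0.04, 0.09, 0.16))
  for (ch in 1:2) target[, , 1, ch, 1] <- err
  mask <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1, 1))
  w <- 0.887
  expect_equal(mse_roi_loss(pred, target, mask, w),
               w * 0.025 + (1 - w) * 0.125)
  # equal weighting averages the two regional means
  expect_equal(mse_roi_loss(pred, target, mask, 0.5 + 1e-9),
               (0.025 + 0.125) / 2, tolerance = 1e-6)
  # perfect prediction
  expect_equal(mse_roi_loss(target, target, mask, w), 0)
  # empty ROI: only the background term contributes
  none <- array(FALSE, c(2, 2, 1, 1))
  expect_equal(mse_roi_loss(pred, target, none, w),
               (1 - w) * mean(target^2))
})

test_that("ROI loss gradient matches finite differences with the weight ratio", {
  set.seed(2)
  pred <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2, 1))
  target <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2, 1))
  mask <- array(runif(4 * 4 * 2) > 0.5, c(4, 4, 2, 1))
  lg <- mse_roi_loss(pred, target, mask, 0.887, gradient = TRUE)
  eps <- 1e-6
  for (i in c(1, 17, 40, 64)) {
    p2 <- pred; p2[i] <- p2[i] + eps
    p1 <- pred; p1[i] <- p1[i] - eps
    gnum <- (mse_roi_loss(p2, target, mask, 0.887) -
               mse_roi_loss(p1, target, mask, 0.887)) / (2 * eps)
    expect_equal(lg$grad[i], gnum, tolerance = 1e-6)
  }
  # an ROI voxel and a background voxel with equal residuals have gradients
  # in the ratio (w / n_roi) : ((1 - w) / n_bg)
  n_roi <- 2 * sum(mask); n_bg <- 2 * sum(!mask)
  i_roi <- which(array(mask, dim(pred)))[1]
  i_bg <- which(!array(mask, dim(pred)))[1]
  r <- (lg$grad[i_roi] / (pred[i_roi] - target[i_roi])) /
    (lg$grad[i_bg] / (pred[i_bg] - target[i_bg]))
  expect_equal(r, (0.887 / n_roi) / (0.113 / n_bg), tolerance = 1e-9)
})

test_that("mask combination is an exhaustive voxel-wise OR", {
  # all 2^4 mask pairs of a 2-voxel volume
  vals <- expand.grid(a1 = c(FALSE, TRUE), a2 = c(FALSE, TRUE),
                      b1 = c(FALSE, TRUE), b2 = c(FALSE, TRUE))
  for (r in seq_len(nrow(vals))) {
    a <- array(c(vals$a1[r], vals$a2[r]), c(2, 1, 1))
    b <- array(c(vals$b1[r], vals$b2[r]), c(2, 1, 1))
    expect_identical(combine_roi_masks(a, b), a | b)
  }
  m <- array(TRUE, c(2, 1, 1))
  expect_identical(combine_roi_masks(m, m), m)
  expect_error(combine_roi_masks(m, array(TRUE, c(3, 1, 1))), "mismatch")
})

test_that("end-to-end network gradients agree with finite differences", {
  cfg <- tiny_net_config()
  p <- build_fdu_net(cfg, seed = 2)
  set.seed(3)
  X <- matrix(rnorm(2 * 6), 2, 6)
  Y <- array(runif(4 * 4 * 2 * 2 * 2), c(4, 4, 2, 2, 2))
  M <- array(runif(4 * 4 * 2 * 2) > 0.6, c(4, 4, 2, 2))
  loss_at <- function(pp) {
    a <- fddot:::fdnet_forward(pp, X, cfg)
    mse_roi_loss(fddot:::unet_forward(pp$un, a$out)$out, Y, M, 0.887)
  }
  a <- fddot:::fdnet_forward(p, X, cfg)
  u <- fddot:::unet_forward(p$un, a$out)
  lg <- mse_roi_loss(u$out, Y, M, 0.887, gradient = TRUE)
  ub <- fddot:::unet_backward(p$un, a$out, u, lg$grad)
  fb <- fddot:::fdnet_backward(p, X, a, ub$dE, cfg)
  eps <- 1e-3
  checks <- list(
    list(get = function() p$fc$w, set = function(v) { q <- p; q$fc$w <- v; q },
         grad = function() fb$fc$w),
    list(get = function() p$ed[[2]]$w,
         set = function(v) { q <- p; q$ed[[2]]$w <- v; q },
         grad = function() fb$ed[[2]]$w),
    list(get = function() p$un$out$w,
         set = function(v) { q <- p; q$un$out$w <- v; q },
         grad = function() ub$grads$out$w))
  set.seed(4)
  for (ck in checks) {
    arr <- ck$get()
    for (i in sample(length(arr), 3)) {
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      gnum <- (loss_at(ck$set(a1)) - loss_at(ck$set(a2))) / (2 * eps)
      gan <- ck$grad()[i]
      expect_equal(gan, gnum, tolerance = 5e-3 + 5e-3 * abs(gnum))
    }
  }
})

test_that("training is seeded, freezes stage-1 weights, and predicts in batch", {
  cfg <- fdunet_config(input_dim = 8, output_dim = c(4, 4, 2),
                       n_encoder_decoder_conv_layers = 2,
                       filters_per_layer = 3, unet_filters = c(2, 3),
                       dropout_rate = 0.1)
  tc <- fdunet_train_config(learning_rate = 0.01, max_epochs = 4,
                            early_stop_patience = 2, batch_size = 4, seed = 9)
  set.seed(1)
  n <- 12
  X <- matrix(rnorm(n * 8), n, 8)
  Y <- array(runif(4 * 4 * 2 * 2 * n, 0.001, 0.02), c(4, 4, 2, 2, n))
  M <- array(runif(4 * 4 * 2 * n) > 0.7, c(4, 4, 2, n))
  m1 <- fdu_net(X, Y, M, config = cfg, train = tc, validation_idx = 11:12)
  m2 <- fdu_net(X, Y, M, config = cfg, train = tc, validation_idx = 11:12)
  expect_identical(m1$params, m2$params)
  # stage 2 never modifies stage-1 weights
  s1_only <- fdunet_train_config(learning_rate = 0.01, max_epochs = 4,
                                 early_stop_patience = 2, batch_size = 4,
                                 seed = 9)
  expect_identical(m1$params$fc, fdu_net(X, Y, M, config = cfg,
                                         train = s1_only,
                                         validation_idx = 11:12)$params$fc)
  # batch prediction equals stacked single predictions (dropout off)
  pb <- predict(m1, X[1:3, ])
  for (i in 1:3) {
    ps <- predict(m1, X[i, ])
    # single-precision convolution kernels: agreement to float accuracy
    expect_equal(ps$mua, pb$mua[, , , i], tolerance = 1e-6)
  }
  expect_true(all(pb$mua > 0) && all(pb$musp > 0))
})
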