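test_that("system normalization is an invertible diagonal scaling", {
  set.seed(11)
  J <- matrix(rnorm(60), 6, 10)
  measured <- rnorm(6) + 3
  est <- runif(10, 0.5, 2)
  resid <- rnorm(6)
  ns <- normalize_system(J, resid, measured, est)
  # undoing both scalings reproduces the original matrix exactly
  back <- sweep(sweep(ns$J, 2, ns$col_scales, `/`), 1, ns$row_scales, `*`)
  expect_equal(back, J, tolerance = 1e-14)
  expect_equal(ns$residual * ns$row_scales, resid, tolerance = 1e-14)
  # homogeneous estimate: one scale per parameter block
  est_h <- c(rep(0.005, 5), rep(1.0, 5))
  ns2 <- normalize_system(J, resid, measured, est_h)
  expect_length(unique(ns2$col_scales[1:5]), 1L)
  expect_length(unique(ns2$col_scales[6:10]), 1L)
  expect_error(normalize_system(J, resid, c(0, measured[-1]), est), "row scale")
  expect_error(normalize_system(J, resid, measured, c(0, est[-1])), "column scale")
})

test_that("regularized update equals a dense oracle and damps with lambda", {
  set.seed(7)
  J <- matrix(rnorm(40), 5, 8)
  dphi <- rnorm(5)
  dmu <- update_step(J, dphi, 0.3)
  oracle <- t(J) %*% solve(J %*% t(J) + 0.3 * diag(5), dphi)
  expect_lt(max(abs(dmu - as.vector(oracle))), 1e-10)
  expect_equal(update_step(J, rep(0, 5), 0.3), rep(0, 8))
  norms <- vapply(c(1, 10, 100, 1000, 1e4), function(l)
    sqrt(sum(update_step(J, dphi, l)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("single update without smoothing equals the dense normal-equations solve", {
  set.seed(21)
  J <- matrix(rnorm(12 * 10), 12, 10)
  dphi <- rnorm(12)
  lambda <- 0.5
  dmu <- update_step(J, dphi, lambda)
  # equivalent over-determined Tikhonov form of the same solution
  alt <- solve(crossprod(J) + lambda * diag(10), crossprod(J, dphi))
  expect_lt(max(abs(dmu - as.vector(alt))), 1e-9)
})

test_that("Gaussian smoothing preserves constants and means", {
  arr <- array(1.5, c(8, 8, 6))
  sm <- gauss_smooth3d(arr, c(8, 8, 8), 4)
  expect_equal(sm, arr, tolerance = 1e-12)
  set.seed(3)
  arr2 <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  sm2 <- gauss_smooth3d(arr2, c(8, 8, 8), 4)
  expect_lt(sd(sm2), sd(arr2))          # smoothing shrinks variance
  expect_equal(dim(sm2), dim(arr2))
})

test_that("reconstruction follows the lambda schedule and the fixed point", {
  g <- mini_geometry()
  pr <- mini_protocol(g)
  cfg <- fd_solver_config(tol = 1e-9)
  vol <- homogeneous_volume(g, 0.005, 1.0)
  ms <- simulate_scan(vol, pr, cfg)
  rec <- dot_reconstruct(ms, pr,
                         fem_recon_config(max_iterations = 6),
                         cfg, initial_background = c(0.005, 1.0))
  # noiseless data from the initial estimate: converged on iteration 1 with a
  # near-zero first update
  expect_true(rec$converged)
  expect_equal(rec$iterations, 1L)
  expect_lt(rec$history$update_norm[1] / sqrt(sum(c(rec$mua, rec$musp)^2)),
            0.05)
  expect_true(all(rec$mua > 0) && all(rec$musp > 0))
  # lambda decays by 10^0.25 per iteration on a perturbed problem
  ms2 <- simulate_scan(homogeneous_volume(g, 0.006, 1.1), pr, cfg)
  rec2 <- dot_reconstruct(ms2, pr, fem_recon_config(max_iterations = 3),
                          cfg, initial_background = c(0.005, 1.0))
  h <- rec2$history
  expect_gte(nrow(h), 2)
  expect_equal(h$lambda[2] / h$lambda[1], 10^-0.25, tolerance = 1e-12)
  # projection error never increases on noiseless self-generated data
  expect_true(all(diff(h$projection_error) <= 1e-9))
})

test_that("hash mismatch between data and protocol is rejected", {
  g <- mini_geometry()
  pr <- mini_protocol(g)
  ms <- simulate_scan(homogeneous_volume(g), pr, fd_solver_config(tol = 1e-8))
  other <- build_scan_protocol(g, probe_layout(c(12, 20)), step_mm = 8,
                               n_x = 2, n_y = 1)
  expect_error(dot_reconstruct(ms, other), "protocol")
})

test_that("a noiseless absorption sphere is recovered at the right place", {
  g <- volume_geometry()
  pr <- build_scan_protocol(g, probe_layout(), step_mm = 8, n_x = 3, n_y = 1)
  cfg <- fd_solver_config(tol = 1e-8)
  # sphere of doubled absorption, top depth 5 mm, centered on the probe row
  ph <- structure(list(
    background_mua = 0.005, background_musp = 1.0,
    anomalies = list(anomaly_spec("sphere", center = c(52, 56, 13),
                                  radius_mm = 8, mua_contrast = 2)),
    seed = 1L), class = "tissue_phantom")
  fine <- rasterize_phantom(ph, fine_grid(g))
  ms <- simulate_scan(fine, pr, cfg)
  rec <- dot_reconstruct(ms, pr, fem_recon_config(max_iterations = 8), cfg,
                         initial_background = c(0.005, 1.0))
  tg <- coarse_target_grid(g)
  truth <- rasterize_phantom(ph, tg)
  # the reconstructed anomaly region shows elevated absorption contrast
  contrast <- mean(rec$mua[truth$mask_mua]) /
    mean(rec$mua[!truth$mask_combined])
  expect_gt(contrast, 1)
  # lateral center of mass of the absorption excess within one coarse voxel
  # of truth (depth is biased shallow with a single-row reflectance
  # protocol -- the classic depth bias of regularized reflectance DOT -- so
  # only in-plane localization is asserted here)
  ctr <- grid_centers(tg)
  w <- pmax(rec$mua - 0.005, 0)
  com <- c(sum(apply(w, 1, sum) * ctr$x), sum(apply(w, 2, sum) * ctr$y))
  com <- com / sum(w)
  expect_true(all(abs(com - c(52, 56)) <= tg$spacing))
})
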