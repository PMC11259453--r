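test_that("zero-frequency solve reduces to the real CW diffusion solution", {
  g <- mini_geometry()
  cfg <- fd_solver_config(modulation_frequency_Hz = 0, tol = 1e-10)
  vol <- homogeneous_volume(g)
  phi <- solve_fd_diffusion(vol, source_point(c(24, 32), 1.0), g, cfg)
  expect_true(max(abs(Im(phi))) <= 1e-12 * max(abs(Re(phi))))
  expect_true(all(Re(phi) > 0))
})

test_that("homogeneous scans attenuate and delay monotonically with separation", {
  g <- mini_geometry()
  pr <- mini_protocol(g)
  cfg <- fd_solver_config(tol = 1e-9)
  ms <- simulate_scan(homogeneous_volume(g), pr, cfg)
  b <- measurement_blocks(ms)
  amp <- matrix(b$logamp, nrow = pr$probe$n_detectors)
  phs <- matrix(b$phase, nrow = pr$probe$n_detectors)
  for (p in seq_len(pr$n_positions)) {
    expect_true(all(diff(amp[, p]) < 0))   # farther detector, dimmer
    expect_true(all(diff(phs[, p]) > 0))   # farther detector, more lag
    expect_true(all(phs[, p] > 0 & phs[, p] < 180))
  }
})

test_that("raising background absorption dims every amplitude channel", {
  g <- mini_geometry()
  pr <- mini_protocol(g)
  cfg <- fd_solver_config(tol = 1e-9)
  lo <- simulate_scan(homogeneous_volume(g, mua = 0.005), pr, cfg)
  hi <- simulate_scan(homogeneous_volume(g, mua = 0.010), pr, cfg)
  expect_true(all(measurement_blocks(hi)$logamp <
                    measurement_blocks(lo)$logamp))
})

test_that("complex measurements obey source-detector reciprocity", {
  g <- mini_geometry()
  cfg <- fd_solver_config(tol = 1e-11)
  set.seed(9)
  tg <- coarse_target_grid(g)
  est <- list(mua = array(0.005 * exp(rnorm(prod(tg$dim), 0, 0.2)), tg$dim),
              musp = array(1.0 * exp(rnorm(prod(tg$dim), 0, 0.2)), tg$dim))
  vol <- prolong_estimate(est, g, c(0.005, 1.0))
  a <- c(20, 32); b <- c(40, 32)
  phi_a <- solve_fd_diffusion(vol, c(a, 1.0), g, cfg)
  phi_b <- solve_fd_diffusion(vol, c(b, 1.0), g, cfg)
  wa <- detector_weights(a, g); wb <- detector_weights(b, g)
  m_ab <- sum(phi_a[wb$index, 1] * wb$weight)
  m_ba <- sum(phi_b[wa$index, 1] * wa$weight)
  expect_lt(Mod(m_ab - m_ba) / Mod(m_ab), 1e-8)
})

test_that("noise model is seeded, unbiased, and matches its configured sd", {
  g <- mini_geometry()
  pr <- mini_protocol(g)
  ms <- simulate_scan(homogeneous_volume(g), pr, fd_solver_config(tol = 1e-9))
  # degenerate model: zero sd leaves the data untouched
  z <- add_noise(ms, noise_model(0, 0, 0, 0), seed = 1)
  expect_equal(z$values, ms$values)
  expect_true(z$noise_applied)
  expect_error(add_noise(z, noise_model(), seed = 1), "already")
  # determinism
  n1 <- add_noise(ms, noise_model(), seed = 7)
  n2 <- add_noise(ms, noise_model(), seed = 7)
  expect_identical(n1$values, n2$values)
  # Monte-Carlo self-consistency of one phase channel over realizations
  model <- noise_model()
  sds <- noise_sd(ms, model)
  ch <- 2L   # phase channel index within the phase block
  nreal <- 1000
  draws <- vapply(seq_len(nreal), function(s)
    measurement_blocks(add_noise(ms, model, seed = s))$phase[ch], numeric(1))
  truth <- measurement_blocks(ms)$phase[ch]
  sd_hat <- sd(draws)
  sd_cfg <- sds$phase_sd_deg[ch]
  se_sd <- sd_cfg / sqrt(2 * (nreal - 1))
  expect_lt(abs(sd_hat - sd_cfg), 3 * se_sd)
  # unbiased in log-amplitude
  amp_draws <- vapply(seq_len(nreal), function(s)
    measurement_blocks(add_noise(ms, model, seed = s))$logamp[1], numeric(1))
  amp_sd <- sds$logamp_sd[1]
  expect_lt(abs(mean(amp_draws) - measurement_blocks(ms)$logamp[1]),
            3 * amp_sd / sqrt(nreal))
})

test_that("measurement sets carry the protocol contract", {
  g <- mini_geometry()
  pr <- mini_protocol(g)
  ms <- simulate_scan(homogeneous_volume(g), pr, fd_solver_config(tol = 1e-8))
  expect_s3_class(ms, "measurement_set")
  expect_length(ms$values, pr$n_channels)
  expect_true(all(is.finite(ms$values)))
  expect_identical(ms$protocol_hash, pr$hash)
})

test_that("the large-grid fallback preconditioner still solves the system", {
  g <- volume_geometry()
  cfg <- fd_solver_config(tol = 1e-6)
  vol <- homogeneous_volume(g, 0.005, 1.0)
  phi <- solve_fd_diffusion(vol, source_point(c(40, 60), 1.0), g, cfg)
  op <- build_diffusion_operator(vol, g, cfg)
  b <- matrix(0 + 0i, prod(g$fine_dim), 1)
  rhs <- fddot:::point_source_rhs(source_point(c(40, 60), 1.0), g)
  b[rhs$index, 1] <- rhs$weight
  ax <- as.matrix(op$K %*% Re(phi)) + 1i * as.matrix(op$K %*% Im(phi)) +
    1i * op$sigma * phi
  rel <- sqrt(sum(Mod(ax - b)^2)) / sqrt(sum(Mod(b)^2))
  expect_lt(rel, 10 * cfg$tol)
})
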