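test_that("phantom sampling is deterministic and respects the table ranges", {
  spec <- dataset_spec()
  g <- volume_geometry()
  for (seed in c(3, 17, 101)) {
    p1 <- sample_phantom(spec, g, seed = seed)
    p2 <- sample_phantom(spec, g, seed = seed)
    expect_identical(p1, p2)
    expect_true(p1$background_mua > 0 && p1$background_musp > 0)
    expect_true(length(p1$anomalies) <= 5)
    for (an in p1$anomalies) {
      expect_true(an$radius_mm >= 5 && an$radius_mm <= 15)
      expect_true(an$depth_mm >= 0 && an$depth_mm <= 20)
      expect_true(an$mua_contrast == 1 ||
                    (an$mua_contrast >= 1.5 && an$mua_contrast <= 3.5))
      expect_true(an$musp_contrast == 1 ||
                    (an$musp_contrast >= 1.5 && an$musp_contrast <= 2.5))
      expect_true(an$mua_contrast != 1 || an$musp_contrast != 1)
      # fully inside the volume
      expect_true(an$depth_mm + an$thickness_mm <= g$extent_mm[3] + 1e-9)
    }
  }
  hom <- sample_phantom(dataset_spec(n_anomalies_range = c(0L, 0L)), g, seed = 1)
  expect_length(hom$anomalies, 0)
})

test_that("rasterization multiplies background by contrast and masks by center test", {
  g <- volume_geometry()
  tg <- coarse_target_grid(g)
  hom <- sample_phantom(dataset_spec(n_anomalies_range = c(0L, 0L)), g, seed = 2)
  rh <- rasterize_phantom(hom, tg)
  expect_true(all(rh$mua == hom$background_mua))
  expect_false(any(rh$mask_combined))
  ph <- structure(list(
    background_mua = 0.005, background_musp = 1.0,
    anomalies = list(anomaly_spec("sphere", center = c(52, 60, 16),
                                  radius_mm = 8, mua_contrast = 2)),
    seed = 1L), class = "tissue_phantom")
  r <- rasterize_phantom(ph, tg)
  expect_equal(sort(unique(as.vector(r$mua))), c(0.005, 0.010))
  expect_true(all(r$mua[r$mask_mua] == 0.010))
  expect_false(any(r$mask_musp))
  # mask voxel count equals a brute-force center-in-sphere test
  ctr <- grid_centers(tg)
  cnt <- 0L
  for (k in seq_len(tg$dim[3])) for (j in seq_len(tg$dim[2]))
    for (i in seq_len(tg$dim[1]))
      if ((ctr$x[i] - 52)^2 + (ctr$y[j] - 60)^2 + (ctr$z[k] - 16)^2 <= 64)
        cnt <- cnt + 1L
  expect_equal(sum(r$mask_mua), cnt)
})

test_that("combined mask is the voxel-wise OR across random phantoms", {
  g <- volume_geometry()
  tg <- coarse_target_grid(g)
  for (seed in 1:8) {
    r <- rasterize_phantom(sample_phantom(dataset_spec(), g, seed = seed), tg)
    expect_identical(r$mask_combined, r$mask_mua | r$mask_musp)
    expect_true(all(r$mua > 0) && all(r$musp > 0))
  }
})

test_that("dataset statistics are complementary and handle degenerate streams", {
  g <- volume_geometry()
  phs <- lapply(1:30, function(s) sample_phantom(dataset_spec(), g, seed = s))
  st <- dataset_statistics(phs, g)
  expect_equal(st$mean_anomaly_fraction + st$background_ratio, 1)
  expect_equal(st$n_examples, 30L)
  hom <- lapply(31:35, function(s)
    sample_phantom(dataset_spec(n_anomalies_range = c(0L, 0L)), g, seed = s))
  sth <- dataset_statistics(hom, g)
  expect_equal(sth$mean_anomaly_fraction, 0)
  expect_equal(sth$background_ratio, 1)
  expect_error(dataset_statistics(list()), "empty")
})

test_that("depth test set carries exactly three single/double-parameter disks", {
  g <- volume_geometry()
  ts <- make_depth_test_set(c(5, 10), n_per_depth = 2L, seed = 4)
  expect_length(ts, 4L)
  for (ex in ts) {
    expect_length(ex$phantom$anomalies, 3L)
    kinds <- vapply(ex$phantom$anomalies, function(a)
      paste(a$mua_contrast != 1, a$musp_contrast != 1), character(1))
    expect_setequal(kinds, c("TRUE FALSE", "FALSE TRUE", "TRUE TRUE"))
    v <- ex$volume
    # a mua-only disk contributes nothing to the musp mask
    a_mua <- ex$phantom$anomalies[[which(kinds == "TRUE FALSE")]]
    tg <- coarse_target_grid(g)
    cc <- grid_centers(tg)
    for (k in seq_len(tg$dim[3])) for (j in seq_len(tg$dim[2]))
      for (i in seq_len(tg$dim[1])) {
        inside <- (cc$x[i] - a_mua$center[1])^2 +
          (cc$y[j] - a_mua$center[2])^2 <= a_mua$radius_mm^2 &&
          abs(cc$z[k] - a_mua$center[3]) <= a_mua$thickness_mm / 2
        if (inside) expect_false(v$mask_musp[i, j, k])
      }
  }
  expect_length(make_depth_test_set(c(5, 10, 15), 3L, seed = 1), 9L)
  expect_error(make_depth_test_set(5, 1L, ring_radius_mm = 4), "overlap")
})
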