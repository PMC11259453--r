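test_that("default linescan protocol reproduces the probe study layout", {
  pr <- build_scan_protocol()
  expect_equal(pr$n_positions, 192L)
  expect_equal(pr$n_pairs, 576L)
  expect_equal(pr$n_channels, 1152L)
  expect_equal(nrow(pr$channels), 1152L)
  # amplitude block first, phase block second, detectors innermost
  expect_equal(unique(pr$channels$kind[1:576]), "log_amplitude")
  expect_equal(unique(pr$channels$kind[577:1152]), "phase")
  expect_equal(pr$channels$detector[1:6], c(1L, 2L, 3L, 1L, 2L, 3L))
  # every probe position keeps the whole detector arm inside the volume
  arm <- max(pr$probe$detector_offsets_mm)
  expect_true(all(pr$positions[, 1] + arm <= pr$geometry$extent_mm[1]))
})

test_that("reduced lattices give the contracted channel count", {
  pr <- build_scan_protocol(step_mm = 16, n_x = 1, n_y = 1)
  expect_equal(pr$n_channels, 6L)  # 1 position x 3 detectors x 2 data kinds
  expect_error(build_scan_protocol(step_mm = 7), "divide")
  tiny <- volume_geometry(extent_mm = c(48, 64, 24), fine_spacing_mm = 4,
                          coarse_spacing_mm = 4, scan_region_mm = 32,
                          target_depth_mm = 16)
  expect_error(
    build_scan_protocol(tiny, probe_layout(c(20, 30, 44)), step_mm = 8),
    "lattice|outside")
})

test_that("coarse target grid is the 16x16x8 scan-region block", {
  g <- volume_geometry()
  tg <- coarse_target_grid(g)
  expect_equal(tg$dim, c(16L, 16L, 8L))
  expect_equal(prod(tg$dim), 2048L)
  expect_equal(tg$origin, c(20, 28, 0))
  ctr <- grid_centers(tg)
  # first voxel center sits half a voxel inside the scan-region origin
  expect_equal(c(ctr$x[1], ctr$y[1], ctr$z[1]), tg$origin + 2)
})

test_that("fine-to-coarse mapping partitions the fine grid", {
  g <- volume_geometry()
  cmap <- fine_to_coarse_map(g)
  expect_equal(dim(cmap), g$fine_dim)
  tg <- coarse_target_grid(g)
  expect_equal(max(cmap), prod(tg$dim))
  # each in-target coarse voxel receives exactly (4/2)^3 = 8 fine cells
  counts <- tabulate(cmap[cmap > 0], nbins = prod(tg$dim))
  expect_true(all(counts == 8L))
  # partition: in-target fine cells + outside cells = all cells
  expect_equal(sum(cmap > 0) + sum(cmap == 0), prod(g$fine_dim))
})

test_that("protocol serialization round-trips and hashes deterministically", {
  pr <- build_scan_protocol(step_mm = 16, n_x = 2, n_y = 3)
  f <- tempfile(fileext = ".yaml")
  write_protocol(pr, f)
  pr2 <- read_protocol(f)
  expect_equal(pr2$positions, pr$positions)
  expect_equal(pr2$channels, pr$channels)
  expect_identical(pr2$hash, pr$hash)
  # byte-identical serialization of two identically built protocols
  f2 <- tempfile(fileext = ".yaml")
  write_protocol(build_scan_protocol(step_mm = 16, n_x = 2, n_y = 3), f2)
  expect_identical(readLines(f), readLines(f2))
  # the hash is sensitive to the layout
  pr3 <- build_scan_protocol(step_mm = 16, n_x = 2, n_y = 2)
  expect_false(identical(pr3$hash, pr$hash))
})

test_that("geometry validation rejects inconsistent spacings", {
  expect_error(volume_geometry(extent_mm = c(105, 120, 50)), "multiple")
  expect_error(volume_geometry(scan_region_mm = 66), "coarse spacing")
})
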