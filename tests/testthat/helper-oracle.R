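# Independent analytic oracle: frequency-domain fluence of a point source in
# a semi-infinite homogeneous medium, extrapolated-boundary (image source)
# solution.  Implemented from the closed form, independent of the package's
# finite-volume solver.
analytic_semiinf_fluence <- function(rho, z, mua, musp, config) {
  kap <- 1 / (3 * (mua + musp))
  k <- sqrt((mua + 1i * config$omega / config$c_medium_mm_s) / kap)
  z0 <- 1 / musp
  zb <- 2 * config$boundary_A * kap
  r1 <- sqrt(rho^2 + (z - z0)^2)
  r2 <- sqrt(rho^2 + (z + z0 + 2 * zb)^2)
  (exp(-k * r1) / r1 - exp(-k * r2) / r2) / (4 * pi * kap)
}

# small test geometry: cheap solves, same code paths as the default
mini_geometry <- function() {
  volume_geometry(extent_mm = c(64, 64, 24), fine_spacing_mm = 4,
                  coarse_spacing_mm = 8, scan_region_mm = 32,
                  target_depth_mm = 16)
}

mini_protocol <- function(geometry = mini_geometry()) {
  build_scan_protocol(geometry, probe_layout(c(12, 20)), step_mm = 8,
                      n_x = 3, n_y = 1)
}

homogeneous_volume <- function(geometry, mua = 0.005, musp = 1.0) {
  list(mua = array(mua, geometry$fine_dim),
       musp = array(musp, geometry$fine_dim))
}
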