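#' Randomized tissue-phantom dataset specification
#'
#' Distribution parameters for the randomized training phantoms: homogeneous
#' background optical properties drawn from truncated normal distributions,
#' and 0-5 tumour-emulating anomalies with uniformly drawn shape, size,
#' depth and contrast.
#'
#' @param bg_mua_mean,bg_mua_sd background absorption mean / sd (mm^-1).
#' @param bg_musp_mean,bg_musp_sd background reduced scattering mean / sd
#'   (mm^-1).
#' @param mua_contrast_range,musp_contrast_range anomaly contrast multiplier
#'   ranges (unitless).
#' @param n_anomalies_range integer range of anomaly counts.
#' @param radius_range_mm anomaly radius range (half-edge for cuboids).
#' @param depth_range_mm range of the anomaly top depth below the surface.
#' @param shapes candidate anomaly shapes.
#' @param floor_mm1 positive floor applied when truncating the background
#'   normals.
#' @return an object of class `"dataset_spec"`.
#' @export
dataset_spec <- function(bg_mua_mean = 0.005, bg_mua_sd = 0.002,
                         bg_musp_mean = 0.98, bg_musp_sd = 0.20,
                         mua_contrast_range = c(1.5, 3.5),
                         musp_contrast_range = c(1.5, 2.5),
                         n_anomalies_range = c(0L, 5L),
                         radius_range_mm = c(5, 15),
                         depth_range_mm = c(0, 20),
                         shapes = c("sphere", "disk", "cuboid"),
                         floor_mm1 = 1e-4) {
  stopifnot(bg_mua_mean > 0, bg_mua_sd > 0, bg_musp_mean > 0, bg_musp_sd > 0,
            diff(mua_contrast_range) >= 0, diff(musp_contrast_range) >= 0,
            diff(n_anomalies_range) >= 0, diff(radius_range_mm) >= 0,
            diff(depth_range_mm) >= 0, floor_mm1 > 0,
            all(shapes %in% c("sphere", "disk", "cuboid")))
  structure(list(bg_mua_mean = bg_mua_mean, bg_mua_sd = bg_mua_sd,
                 bg_musp_mean = bg_musp_mean, bg_musp_sd = bg_musp_sd,
                 mua_contrast_range = mua_contrast_range,
                 musp_contrast_range = musp_contrast_range,
                 n_anomalies_range = as.integer(n_anomalies_range),
                 radius_range_mm = radius_range_mm,
                 depth_range_mm = depth_range_mm,
                 shapes = shapes, floor_mm1 = floor_mm1),
            class = "dataset_spec")
}

# one positive truncated-normal draw
rtnorm1 <- function(mean, sd, floor) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > floor) return(x)
  }
  stop("truncated normal sampler failed; check mean/sd against the floor")
}

#' Sample one randomized tissue phantom
#'
#' Backgrounds are truncated normal; the anomaly count is uniform on its
#' integer range; contrasts are uniform on their ranges; the perturbation
#' kind of every anomaly is uniform over mu_a-only / mu_s'-only / both.  All
#' three shapes share a common bounding box of 2r per axis (ball, vertical
#' cylinder of height 2r, cube of edge 2r), and anomalies are placed fully
#' inside the lateral footprint of the scan region, with the anomaly top at
#' the drawn depth.  Deterministic given `seed`.
#'
#' @param spec a [dataset_spec()].
#' @param geometry a [volume_geometry()].
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @param max_retries placement retries per anomaly before it is dropped
#'   with a warning.
#' @return an object of class `"tissue_phantom"`: `background_mua`,
#'   `background_musp`, `anomalies` (list of anomaly specs), `seed`.
#' @export
sample_phantom <- function(spec = dataset_spec(), geometry = volume_geometry(),
                           seed = NULL, max_retries = 25L) {
  stopifnot(inherits(spec, "dataset_spec"), inherits(geometry, "volume_geometry"))
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  bg_mua <- rtnorm1(spec$bg_mua_mean, spec$bg_mua_sd, spec$floor_mm1)
  bg_musp <- rtnorm1(spec$bg_musp_mean, spec$bg_musp_sd, spec$floor_mm1)
  n_an <- if (spec$n_anomalies_range[1] == spec$n_anomalies_range[2])
    spec$n_anomalies_range[1]
  else sample(seq(spec$n_anomalies_range[1], spec$n_anomalies_range[2]), 1)
  x_lo <- geometry$scan_origin_mm[1]; x_hi <- x_lo + geometry$scan_region_mm
  y_lo <- geometry$scan_origin_mm[2]; y_hi <- y_lo + geometry$scan_region_mm
  anomalies <- list()
  if (n_an > 0) for (a in seq_len(n_an)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      r <- stats::runif(1, spec$radius_range_mm[1], spec$radius_range_mm[2])
      depth <- stats::runif(1, spec$depth_range_mm[1], spec$depth_range_mm[2])
      shape <- spec$shapes[sample(length(spec$shapes), 1)]
      kind <- c("mua_only", "musp_only", "both")[sample(3, 1)]
      if (x_lo + r > x_hi - r || y_lo + r > y_hi - r ||
          depth + 2 * r > geometry$extent_mm[3]) next
      ctr <- c(stats::runif(1, x_lo + r, x_hi - r),
               stats::runif(1, y_lo + r, y_hi - r))
      mua_c <- if (kind %in% c("mua_only", "both"))
        stats::runif(1, spec$mua_contrast_range[1], spec$mua_contrast_range[2]) else 1
      musp_c <- if (kind %in% c("musp_only", "both"))
        stats::runif(1, spec$musp_contrast_range[1], spec$musp_contrast_range[2]) else 1
      anomalies[[length(anomalies) + 1L]] <- anomaly_spec(
        shape = shape, center = c(ctr, depth + r), radius_mm = r,
        thickness_mm = 2 * r, depth_mm = depth,
        mua_contrast = mua_c, musp_contrast = musp_c)
      placed <- TRUE
      break
    }
    if (!placed)
      warning("anomaly dropped: no placement found inside the volume")
  }
  structure(list(background_mua = bg_mua, background_musp = bg_musp,
                 anomalies = anomalies, seed = seed),
            class = "tissue_phantom")
}

#' Explicit anomaly description
#'
#' @param shape one of `"sphere"`, `"disk"`, `"cuboid"`.
#' @param center (x, y, z) of the anomaly center, mm.
#' @param radius_mm sphere/disk radius; half-edge for cuboids.
#' @param thickness_mm disk/cuboid height (ignored for spheres).
#' @param depth_mm depth of the anomaly top below the surface (provenance;
#'   the geometry is fully defined by `center`/`radius_mm`/`thickness_mm`).
#' @param mua_contrast,musp_contrast multiplicative contrasts; 1 for an
#'   unperturbed parameter.
#' @return a list of class `"anomaly_spec"`.
#' @export
anomaly_spec <- function(shape, center, radius_mm, thickness_mm = 2 * radius_mm,
                         depth_mm = center[3] - thickness_mm / 2,
                         mua_contrast = 1, musp_contrast = 1) {
  shape <- match.arg(shape, c("sphere", "disk", "cuboid"))
  stopifnot(length(center) == 3, radius_mm > 0, thickness_mm > 0,
            mua_contrast > 0, musp_contrast > 0)
  structure(list(shape = shape, center = as.numeric(center),
                 radius_mm = radius_mm, thickness_mm = thickness_mm,
                 depth_mm = depth_mm,
                 mua_contrast = mua_contrast, musp_contrast = musp_contrast),
            class = "anomaly_spec")
}

# logical membership of grid centers (vectors x,y,z of equal length) in an anomaly
anomaly_membership <- function(an, x, y, z) {
  switch(an$shape,
    sphere = (x - an$center[1])^2 + (y - an$center[2])^2 +
             (z - an$center[3])^2 <= an$radius_mm^2,
    disk = (x - an$center[1])^2 + (y - an$center[2])^2 <= an$radius_mm^2 &
           abs(z - an$center[3]) <= an$thickness_mm / 2,
    cuboid = abs(x - an$center[1]) <= an$radius_mm &
             abs(y - an$center[2]) <= an$radius_mm &
             abs(z - an$center[3]) <= an$thickness_mm / 2)
}

#' Rasterize a phantom to an optical volume with ROI masks
#'
#' Voxel values are background times contrast inside an anomaly (a voxel
#' belongs to an anomaly when its center lies inside it; later anomalies
#' overwrite earlier ones on overlap).  The per-parameter ROI masks mark
#' voxels inside any anomaly perturbing that parameter, and the combined
#' mask is their voxel-wise OR.
#'
#' @param phantom a [sample_phantom()] / `"tissue_phantom"` object.
#' @param grid a grid description (`origin`, `spacing`, `dim`), e.g. from
#'   [coarse_target_grid()] or [fine_grid()].
#' @return list with 3D arrays `mua`, `musp` (mm^-1) and logical arrays
#'   `mask_mua`, `mask_musp`, `mask_combined`.
#' @export
rasterize_phantom <- function(phantom, grid) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            all(c("origin", "spacing", "dim") %in% names(grid)))
  cc <- grid_center_arrays(grid)
  X <- cc$X; Y <- cc$Y; Z <- cc$Z
  d <- grid$dim
  mua <- array(phantom$background_mua, d)
  musp <- array(phantom$background_musp, d)
  mask_mua <- array(FALSE, d); mask_musp <- array(FALSE, d)
  for (an in phantom$anomalies) {
    inn <- anomaly_membership(an, X, Y, Z)
    # later anomalies overwrite earlier ones on overlap (both parameters);
    # masks mark only the parameter(s) an anomaly actually perturbs, OR-ed
    mua[inn] <- phantom$background_mua * an$mua_contrast
    musp[inn] <- phantom$background_musp * an$musp_contrast
    if (an$mua_contrast != 1) mask_mua <- mask_mua | inn
    if (an$musp_contrast != 1) mask_musp <- mask_musp | inn
  }
  list(mua = mua, musp = musp,
       mask_mua = mask_mua, mask_musp = mask_musp,
       mask_combined = mask_mua | mask_musp)
}

#' Fine-grid description of the full simulation volume
#' @param geometry a [volume_geometry()].
#' @return list with `origin`, `spacing`, `dim`.
#' @export
fine_grid <- function(geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  list(origin = c(0, 0, 0), spacing = geometry$fine_spacing_mm,
       dim = geometry$fine_dim)
}

#' Summary statistics of a generated dataset
#'
#' Computes, over a stream of rasterized examples on the coarse target grid,
#' the mean fraction of voxels covered by the combined anomaly mask, its
#' complement (the background ratio), and the mean background optical
#' properties.
#'
#' @param examples list of rasterized examples (each as returned by
#'   [rasterize_phantom()] on the target grid), or a list of
#'   `"tissue_phantom"` objects together with `geometry`.
#' @param geometry required when `examples` are phantoms.
#' @return list with `mean_anomaly_fraction`, `sd_anomaly_fraction`,
#'   `background_ratio`, `mean_background_mua`, `mean_background_musp`,
#'   `n_examples`.
#' @export
dataset_statistics <- function(examples, geometry = NULL) {
  if (length(examples) == 0) stop("empty example stream")
  if (inherits(examples[[1]], "tissue_phantom")) {
    stopifnot(inherits(geometry, "volume_geometry"))
    tg <- coarse_target_grid(geometry)
    fr <- vapply(examples, function(p)
      mean(rasterize_phantom(p, tg)$mask_combined), numeric(1))
    mua <- vapply(examples, function(p) p$background_mua, numeric(1))
    musp <- vapply(examples, function(p) p$background_musp, numeric(1))
  } else {
    fr <- vapply(examples, function(e) mean(e$mask_combined), numeric(1))
    mua <- vapply(examples, function(e)
      stats::median(e$mua[!e$mask_combined]), numeric(1))
    musp <- vapply(examples, function(e)
      stats::median(e$musp[!e$mask_combined]), numeric(1))
  }
  list(mean_anomaly_fraction = mean(fr),
       sd_anomaly_fraction = stats::sd(fr),
       background_ratio = 1 - mean(fr),
       mean_background_mua = mean(mua),
       mean_background_musp = mean(musp),
       n_examples = length(examples))
}

#' Fixed three-disk depth test set
#'
#' Builds the depth-sensitivity test set: each volume carries exactly three
#' disk-shaped anomalies (radius 8 mm, thickness 5 mm) at a common depth --
#' one perturbing only mu_a, one only mu_s', one both -- laterally separated
#' at 120 degrees around the scan-region center.  Backgrounds and contrasts
#' are resampled per volume from the dataset spec.
#'
#' @param depths_mm anomaly top depths to test.
#' @param n_per_depth volumes per depth.
#' @param spec a [dataset_spec()].
#' @param geometry a [volume_geometry()].
#' @param seed integer seed.
#' @param radius_mm,thickness_mm disk dimensions.
#' @param ring_radius_mm circumradius of the three disk centers.
#' @return list of examples; each has `phantom`, `depth_mm`, plus the
#'   rasterized target-grid `volume` (with masks).
#' @export
make_depth_test_set <- function(depths_mm = c(2.5, 5, 7.5, 10, 15),
                                n_per_depth = 30L,
                                spec = dataset_spec(),
                                geometry = volume_geometry(),
                                seed = 1L,
                                radius_mm = 8, thickness_mm = 5,
                                ring_radius_mm = 18) {
  stopifnot(n_per_depth >= 1, all(depths_mm >= 0))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  ctr0 <- c(geometry$scan_origin_mm[1] + geometry$scan_region_mm / 2,
            geometry$scan_origin_mm[2] + geometry$scan_region_mm / 2)
  ang <- (0:2) * 2 * pi / 3 + pi / 2
  offs <- cbind(ring_radius_mm * cos(ang), ring_radius_mm * sin(ang))
  if (min(stats::dist(offs)) < 2 * radius_mm)
    stop("disk layout error: disks would overlap")
  tg <- coarse_target_grid(geometry)
  out <- list()
  for (depth in depths_mm) {
    if (depth + thickness_mm > geometry$extent_mm[3])
      stop("depth outside the volume")
    for (i in seq_len(n_per_depth)) {
      bg_mua <- rtnorm1(spec$bg_mua_mean, spec$bg_mua_sd, spec$floor_mm1)
      bg_musp <- rtnorm1(spec$bg_musp_mean, spec$bg_musp_sd, spec$floor_mm1)
      kinds <- c("mua_only", "musp_only", "both")
      anomalies <- lapply(1:3, function(j) {
        mua_c <- if (kinds[j] %in% c("mua_only", "both"))
          stats::runif(1, spec$mua_contrast_range[1], spec$mua_contrast_range[2]) else 1
        musp_c <- if (kinds[j] %in% c("musp_only", "both"))
          stats::runif(1, spec$musp_contrast_range[1], spec$musp_contrast_range[2]) else 1
        anomaly_spec(shape = "disk",
                     center = c(ctr0 + offs[j, ], depth + thickness_mm / 2),
                     radius_mm = radius_mm, thickness_mm = thickness_mm,
                     depth_mm = depth,
                     mua_contrast = mua_c, musp_contrast = musp_c)
      })
      ph <- structure(list(background_mua = bg_mua, background_musp = bg_musp,
                           anomalies = anomalies, seed = NA_integer_),
                      class = "tissue_phantom")
      out[[length(out) + 1L]] <- list(phantom = ph, depth_mm = depth,
                                      volume = rasterize_phantom(ph, tg))
    }
  }
  out
}

# memoized voxel-center coordinate arrays per grid
.grid_cache <- new.env(parent = emptyenv())
grid_center_arrays <- function(grid) {
  key <- paste(c(grid$origin, grid$spacing, grid$dim), collapse = "|")
  got <- get0(key, envir = .grid_cache)
  if (!is.null(got)) return(got)
  ctr <- grid_centers(grid)
  d <- grid$dim
  out <- list(X = array(rep(ctr$x, times = d[2] * d[3]), d),
              Y = array(rep(rep(ctr$y, each = d[1]), times = d[3]), d),
              Z = array(rep(ctr$z, each = d[1] * d[2]), d))
  assign(key, out, envir = .grid_cache)
  out
}

# save/restore the global RNG state so seeded helpers do not disturb callers
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
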