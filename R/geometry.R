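#' Volume geometry for the simulation slab
#'
#' Defines the cuboid tissue volume probed from its top surface, together with
#' the two regular grids used throughout: a fine cell-centered grid on which
#' the diffusion forward problem is solved, and a coarse grid that forms the
#' reconstruction basis / network target.
#'
#' Coordinates are right-handed, in millimetres, with the origin at one corner
#' of the top surface and z increasing downward into the tissue.  All voxel
#' indexing is 0-based in documentation and half-open `[lo, hi)` in space;
#' R-side arrays are 1-based as usual.
#'
#' @param extent_mm numeric length-3, volume extent (x, y, z) in mm.
#' @param fine_spacing_mm fine (forward-solve) grid spacing in mm.
#' @param coarse_spacing_mm coarse (reconstruction basis) spacing in mm.
#' @param scan_region_mm side length of the square scan region on the top
#'   face, centered on the volume.
#' @param target_depth_mm depth extent of the reconstruction target block.
#' @return an object of class `"volume_geometry"`.
#' @export
volume_geometry <- function(extent_mm = c(104, 120, 50),
                            fine_spacing_mm = 2,
                            coarse_spacing_mm = 4,
                            scan_region_mm = 64,
                            target_depth_mm = 32) {
  stopifnot(length(extent_mm) == 3, all(extent_mm > 0),
            fine_spacing_mm > 0, coarse_spacing_mm > 0)
  if (any(abs(extent_mm / fine_spacing_mm -
              round(extent_mm / fine_spacing_mm)) > 1e-9))
    stop("volume extents must be integer multiples of the fine spacing")
  for (v in c(scan_region_mm, target_depth_mm))
    if (abs(v / coarse_spacing_mm - round(v / coarse_spacing_mm)) > 1e-9)
      stop("scan region and target depth must be multiples of the coarse spacing")
  if (scan_region_mm > min(extent_mm[1:2]))
    stop("scan region does not fit inside the volume")
  g <- list(extent_mm = as.numeric(extent_mm),
            fine_spacing_mm = fine_spacing_mm,
            coarse_spacing_mm = coarse_spacing_mm,
            scan_region_mm = scan_region_mm,
            target_depth_mm = target_depth_mm,
            fine_dim = as.integer(round(extent_mm / fine_spacing_mm)),
            scan_origin_mm = c((extent_mm[1] - scan_region_mm) / 2,
                               (extent_mm[2] - scan_region_mm) / 2))
  class(g) <- "volume_geometry"
  g
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("FD-DOT volume geometry\n")
  cat(sprintf("  extent      : %g x %g x %g mm (z downward from the probed surface)\n",
              x$extent_mm[1], x$extent_mm[2], x$extent_mm[3]))
  cat(sprintf("  fine grid   : %d x %d x %d cells at %g mm\n",
              x$fine_dim[1], x$fine_dim[2], x$fine_dim[3], x$fine_spacing_mm))
  tg <- coarse_target_grid(x)
  cat(sprintf("  target grid : %d x %d x %d voxels at %g mm over the %g mm scan region\n",
              tg$dim[1], tg$dim[2], tg$dim[3], x$coarse_spacing_mm,
              x$scan_region_mm))
  invisible(x)
}

#' Handheld probe layout
#'
#' A single source with in-line detectors at fixed separations along the scan
#' (x) axis.
#'
#' @param detector_offsets_mm detector separations from the source, mm.
#' @return an object of class `"probe_layout"`.
#' @export
probe_layout <- function(detector_offsets_mm = c(20, 30, 40)) {
  stopifnot(length(detector_offsets_mm) >= 1, all(detector_offsets_mm > 0),
            all(diff(detector_offsets_mm) > 0))
  structure(list(detector_offsets_mm = as.numeric(detector_offsets_mm),
                 n_detectors = length(detector_offsets_mm)),
            class = "probe_layout")
}

#' Fine-grid cell-center coordinates along one axis
#' @keywords internal
fine_centers <- function(geometry, axis) {
  h <- geometry$fine_spacing_mm
  (seq_len(geometry$fine_dim[axis]) - 0.5) * h
}

#' Build the linescan measurement protocol
#'
#' Lays out the ordered probe positions of the linescan acquisition and the
#' ordered measurement channel table.  Probe positions form a regular lattice
#' at `step_mm` pitch: the y positions span the scan region (row-major, y
#' outer) and the x positions are chosen so that the source plus the longest
#' detector arm stays at least one step inside the volume edge, while the
#' number of x positions times the step covers the scan-region width.  With
#' the default geometry and probe this gives 12 x 16 = 192 positions, hence
#' 576 source/detector pairs and 1152 measurement channels (all log-amplitude
#' channels first, then all phase channels, position-major with detectors
#' innermost).
#'
#' @param geometry a [volume_geometry()].
#' @param probe a [probe_layout()].
#' @param step_mm scan increment in mm.
#' @param n_x,n_y optional number of probe positions per axis; defaults give
#'   the full linescan lattice. Reduced lattices keep the same centering.
#' @return an object of class `"scan_protocol"` with elements `positions`
#'   (n x 2 matrix of source x, y), `channels` (data frame with columns
#'   `position`, `detector`, `kind`), and provenance fields.
#' @export
build_scan_protocol <- function(geometry = volume_geometry(),
                                probe = probe_layout(),
                                step_mm = 4,
                                n_x = NULL, n_y = NULL) {
  stopifnot(inherits(geometry, "volume_geometry"), inherits(probe, "probe_layout"),
            step_mm > 0)
  if (abs(geometry$scan_region_mm / step_mm -
          round(geometry$scan_region_mm / step_mm)) > 1e-9)
    stop("step must divide the scan-region side")
  arm <- max(probe$detector_offsets_mm)
  if (is.null(n_y)) n_y <- as.integer(geometry$scan_region_mm / step_mm)
  # the x lattice is shortened relative to y so the detector arm stays inside
  # the volume; with the default geometry this gives the 12 x 16 linescan
  # lattice (192 positions, 576 source/detector pairs)
  if (is.null(n_x)) n_x <- as.integer(round(0.75 * geometry$scan_region_mm / step_mm))
  stopifnot(n_x >= 1, n_y >= 1)
  x_lo <- step_mm
  x_hi <- geometry$extent_mm[1] - arm - step_mm
  span_x <- (n_x - 1) * step_mm
  if (span_x > x_hi - x_lo)
    stop("probe lattice too wide for the volume with this detector arm")
  # center the mean source/detector midpoint on the scan region, snapped to
  # the step lattice anchored at the scan-region origin, then clamp so the
  # arm stays >= one step inside the volume edge
  ctr <- geometry$scan_origin_mm[1] + geometry$scan_region_mm / 2 -
    mean(probe$detector_offsets_mm) / 2
  x0 <- geometry$scan_origin_mm[1] +
    step_mm * round((ctr - span_x / 2 - geometry$scan_origin_mm[1]) / step_mm)
  x0 <- min(max(x0, x_lo), x_hi - span_x)
  xs <- x0 + (seq_len(n_x) - 1) * step_mm
  span_y <- (n_y - 1) * step_mm
  y0 <- geometry$scan_origin_mm[2] + (geometry$scan_region_mm - step_mm - span_y) / 2
  ys <- y0 + (seq_len(n_y) - 1) * step_mm
  # row-major over y then x: y outer, x inner
  pos <- cbind(x = rep(xs, times = n_y), y = rep(ys, each = n_x))
  for (p in seq_len(nrow(pos))) {
    dx <- pos[p, 1] + probe$detector_offsets_mm
    if (pos[p, 1] < 0 || pos[p, 1] > geometry$extent_mm[1] ||
        pos[p, 2] < 0 || pos[p, 2] > geometry$extent_mm[2] ||
        any(dx < 0 | dx > geometry$extent_mm[1]))
      stop(sprintf("probe position %d at (%g, %g) places a detector outside the volume",
                   p, pos[p, 1], pos[p, 2]))
  }
  n_pairs <- nrow(pos) * probe$n_detectors
  base <- data.frame(position = rep(seq_len(nrow(pos)), each = probe$n_detectors),
                     detector = rep(seq_len(probe$n_detectors), times = nrow(pos)))
  channels <- rbind(cbind(base, kind = "log_amplitude"),
                    cbind(base, kind = "phase"))
  rownames(channels) <- NULL
  pr <- list(geometry = geometry, probe = probe, step_mm = step_mm,
             positions = pos, channels = channels,
             n_positions = nrow(pos), n_pairs = n_pairs,
             n_channels = 2L * n_pairs)
  pr$hash <- protocol_hash(pr)
  class(pr) <- "scan_protocol"
  pr
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat("FD-DOT linescan protocol\n")
  cat(sprintf("  %d probe positions at %g mm pitch, %d detectors (%s mm)\n",
              x$n_positions, x$step_mm, x$probe$n_detectors,
              paste(x$probe$detector_offsets_mm, collapse = "/")))
  cat(sprintf("  %d source/detector pairs -> %d channels (log-amplitude then phase)\n",
              x$n_pairs, x$n_channels))
  cat(sprintf("  protocol hash %s\n", x$hash))
  invisible(x)
}

#' Coarse reconstruction / target grid
#'
#' The coarse basis aligned to the scan region, from the surface down to the
#' target depth; voxels are half-open `[lo, hi)` cubes of the coarse spacing.
#' With the default geometry this is the 16 x 16 x 8 block (2048 voxels per
#' optical parameter).
#'
#' @param geometry a [volume_geometry()].
#' @return list with `origin` (mm, length 3), `spacing` (mm) and `dim`
#'   (integer length 3).
#' @export
coarse_target_grid <- function(geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  s <- geometry$coarse_spacing_mm
  list(origin = c(geometry$scan_origin_mm, 0),
       spacing = s,
       dim = as.integer(round(c(geometry$scan_region_mm / s,
                                geometry$scan_region_mm / s,
                                geometry$target_depth_mm / s))))
}

#' Voxel-center coordinates of a coarse grid
#' @param grid a grid description from [coarse_target_grid()].
#' @return list of numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_centers <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$spacing,
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$spacing,
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$spacing)
}

#' Map fine cells to coarse target voxels
#'
#' Each fine cell belongs to exactly one coarse voxel, or to "outside" (0)
#' when its center falls off the target block; the mapping is a partition.
#'
#' @param geometry a [volume_geometry()].
#' @return integer array of fine-grid shape with the linear coarse-voxel
#'   index (1..prod(dim)) or 0 for cells outside the target block.
#' @export
fine_to_coarse_map <- function(geometry) {
  tg <- coarse_target_grid(geometry)
  cx <- fine_centers(geometry, 1); cy <- fine_centers(geometry, 2)
  cz <- fine_centers(geometry, 3)
  ix <- floor((cx - tg$origin[1]) / tg$spacing)
  iy <- floor((cy - tg$origin[2]) / tg$spacing)
  iz <- floor((cz - tg$origin[3]) / tg$spacing)
  ok_x <- ix >= 0 & ix < tg$dim[1]
  ok_y <- iy >= 0 & iy < tg$dim[2]
  ok_z <- iz >= 0 & iz < tg$dim[3]
  out <- array(0L, geometry$fine_dim)
  okg <- outer(outer(ok_x, ok_y, "&"), ok_z, "&")
  lin <- outer(outer(pmax(ix, 0L) + 1L, pmax(iy, 0L) * tg$dim[1], "+"),
               pmax(iz, 0L) * tg$dim[1] * tg$dim[2], "+")
  out[okg] <- as.integer(lin[okg])
  out
}

#' Serialize a scan protocol to a YAML file
#'
#' The file holds geometry, probe offsets, step, the explicit position list
#' and the ordered channel table, so a measurement vector can always be
#' interpreted against the exact layout it was produced with.
#'
#' @param protocol a [build_scan_protocol()] object.
#' @param path file path.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "scan_protocol"))
  g <- protocol$geometry
  obj <- list(
    geometry = list(extent_mm = g$extent_mm,
                    fine_spacing_mm = g$fine_spacing_mm,
                    coarse_spacing_mm = g$coarse_spacing_mm,
                    scan_region_mm = g$scan_region_mm,
                    target_depth_mm = g$target_depth_mm),
    probe = list(detector_offsets_mm = protocol$probe$detector_offsets_mm),
    step_mm = protocol$step_mm,
    positions = lapply(seq_len(protocol$n_positions),
                       function(i) as.numeric(protocol$positions[i, ])),
    channels = list(position = protocol$channels$position,
                    detector = protocol$channels$detector,
                    kind = protocol$channels$kind))
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' Read a scan protocol back from YAML
#' @param path file path written by [write_protocol()].
#' @return a `"scan_protocol"` object.
#' @export
read_protocol <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- do.call(volume_geometry, obj$geometry)
  probe <- probe_layout(obj$probe$detector_offsets_mm)
  pos <- do.call(rbind, obj$positions)
  colnames(pos) <- c("x", "y")
  channels <- data.frame(position = as.integer(obj$channels$position),
                         detector = as.integer(obj$channels$detector),
                         kind = obj$channels$kind)
  pr <- list(geometry = g, probe = probe, step_mm = obj$step_mm,
             positions = pos, channels = channels,
             n_positions = nrow(pos),
             n_pairs = nrow(pos) * probe$n_detectors,
             n_channels = nrow(channels))
  pr$hash <- protocol_hash(pr)
  class(pr) <- "scan_protocol"
  pr
}

#' Stable content hash of a scan protocol
#'
#' 32-bit FNV-1a over a canonical text rendering; used to tie measurement
#' vectors, normalization statistics and trained models to the channel layout
#' they were produced with.
#'
#' @param protocol a `"scan_protocol"` object.
#' @return hex string.
#' @export
protocol_hash <- function(protocol) {
  g <- protocol$geometry
  txt <- paste(
    paste(format(g$extent_mm, digits = 12), collapse = ","),
    format(g$fine_spacing_mm, digits = 12), format(g$coarse_spacing_mm, digits = 12),
    format(g$scan_region_mm, digits = 12), format(g$target_depth_mm, digits = 12),
    paste(format(protocol$probe$detector_offsets_mm, digits = 12), collapse = ","),
    format(protocol$step_mm, digits = 12),
    paste(format(t(protocol$positions), digits = 12), collapse = ","),
    paste(protocol$channels$position, protocol$channels$detector,
          protocol$channels$kind, collapse = ";"),
    sep = "|")
  fnv1a32(txt)
}

#' @keywords internal
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  p <- 16777619
  m <- 2^32
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31) , b) + (h >= 2^31) * 2^31
    # keep arithmetic in doubles: xor low 31 bits, carry top bit through
    h <- (h * p) %% m
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
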