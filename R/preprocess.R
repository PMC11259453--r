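#' Fit per-channel input normalization statistics
#'
#' Computes, on training measurements only, the per-channel center and scale
#' used to normalize network inputs: z-score (mean/sd, the default) or
#' min-max (minimum/range, available for comparison).  Channels with
#' (near-)zero scale are floored at 1e-12 with a warning, so constant
#' channels transform to zero.
#'
#' @param measurements numeric matrix, examples in rows, channels in
#'   columns (the layout of [simulate_scan()] values).
#' @param method `"zscore"` or `"minmax"`.
#' @param protocol_hash optional hash tying the stats to a channel layout.
#' @return an object of class `"normalization_stats"`.
#' @export
fit_input_stats <- function(measurements, method = c("zscore", "minmax"),
                            protocol_hash = NULL) {
  method <- match.arg(method)
  measurements <- as.matrix(measurements)
  if (nrow(measurements) < 2)
    stop("at least 2 training examples are required to fit input statistics")
  if (method == "zscore") {
    center <- colMeans(measurements)
    scale <- apply(measurements, 2, stats::sd)
  } else {
    center <- apply(measurements, 2, min)
    scale <- apply(measurements, 2, max) - center
  }
  dead <- scale < 1e-12
  if (any(dead)) {
    warning(sprintf("%d constant channel(s); scale floored at 1e-12", sum(dead)))
    scale[dead] <- 1e-12
  }
  structure(list(kind = "input", method = method,
                 center = center, scale = scale,
                 protocol_hash = protocol_hash,
                 fitted_on = dataset_fingerprint(measurements)),
            class = "normalization_stats")
}

#' Apply fitted input normalization
#' @param measurements matrix (examples x channels) or vector.
#' @param stats a fitted input [fit_input_stats()] object.
#' @return transformed matrix of the same shape.
#' @export
apply_input_stats <- function(measurements, stats) {
  stopifnot(inherits(stats, "normalization_stats"), stats$kind == "input")
  v <- if (is.null(dim(measurements))) matrix(measurements, nrow = 1)
       else as.matrix(measurements)
  stopifnot(ncol(v) == length(stats$center))
  out <- sweep(sweep(v, 2, stats$center, `-`), 2, stats$scale, `/`)
  if (is.null(dim(measurements))) as.vector(out) else out
}

#' Fit global min-max target statistics
#'
#' The global per-parameter minimum and range across the training-set target
#' volumes; targets are mapped by `(x - min) / range` and predictions are
#' mapped back exactly.
#'
#' @param targets numeric array (n x X x Y x Z x 2) or list of
#'   (X x Y x Z x 2) arrays; channel 1 is mu_a, channel 2 mu_s'.
#' @return an object of class `"normalization_stats"`.
#' @export
fit_target_stats <- function(targets) {
  if (is.list(targets)) targets <- simplify2array(targets)  # dims ... x n
  stopifnot(is.array(targets), dim(targets)[4] == 2)
  ch_dim <- 4L   # layout [x, y, z, channel(, n)]
  mins <- ranges <- numeric(2)
  for (ch in 1:2) {
    sl <- slice_channel(targets, ch_dim, ch)
    mins[ch] <- min(sl); ranges[ch] <- max(sl) - mins[ch]
  }
  if (any(ranges <= 0)) stop("degenerate target range")
  structure(list(kind = "target", min = mins, range = ranges,
                 fitted_on = dataset_fingerprint(as.numeric(targets))),
            class = "normalization_stats")
}

slice_channel <- function(arr, ch_dim, ch) {
  idx <- rep(list(quote(expr = )), length(dim(arr)))
  idx[[ch_dim]] <- ch
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Min-max normalize target volumes / invert on predictions
#'
#' @param vol array whose last (or 4th) length-2 dimension indexes the
#'   (mu_a, mu_s') channels.
#' @param stats a fitted target [fit_target_stats()] object.
#' @return array of the same shape.
#' @export
normalize_targets <- function(vol, stats) {
  stopifnot(inherits(stats, "normalization_stats"), stats$kind == "target")
  transform_channels(vol, function(x, ch) (x - stats$min[ch]) / stats$range[ch])
}

#' @rdname normalize_targets
#' @param pred normalized prediction array.
#' @export
denormalize_predictions <- function(pred, stats) {
  stopifnot(inherits(stats, "normalization_stats"), stats$kind == "target")
  transform_channels(pred, function(x, ch) x * stats$range[ch] + stats$min[ch])
}

transform_channels <- function(vol, f) {
  stopifnot(dim(vol)[4] == 2)
  ch_dim <- 4L
  out <- vol
  for (ch in 1:2) {
    idx <- rep(list(quote(expr = )), length(dim(vol)))
    idx[[ch_dim]] <- ch
    sl <- do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx, list(f(sl, ch))))
  }
  out
}

dataset_fingerprint <- function(x) {
  x <- as.numeric(as.matrix(x))
  fnv1a32(paste(length(x), format(sum(x), digits = 15),
                format(sum(x^2), digits = 15), sep = "|"))
}

# 1D Catmull-Rom interpolation matrix from source cell centers to query
# points (both in the same physical coordinate), clamped at the edges
interp_matrix_1d <- function(src, query, method = c("bicubic", "trilinear")) {
  method <- match.arg(method)
  h <- src[2] - src[1]
  n <- length(src)
  W <- matrix(0, length(query), n)
  for (q in seq_along(query)) {
    t <- (query[q] - src[1]) / h
    i <- floor(t); u <- t - i
    i <- i + 1                       # 1-based index of the left sample
    if (method == "trilinear") {
      ids <- c(i, i + 1); w <- c(1 - u, u)
    } else {
      ids <- c(i - 1, i, i + 1, i + 2)
      w <- c(-0.5 * u^3 + u^2 - 0.5 * u,
             1.5 * u^3 - 2.5 * u^2 + 1,
             -1.5 * u^3 + 2 * u^2 + 0.5 * u,
             0.5 * u^3 - 0.5 * u^2)
    }
    ids <- pmin(pmax(ids, 1), n)     # clamped edge handling
    for (m in seq_along(ids)) W[q, ids[m]] <- W[q, ids[m]] + w[m]
  }
  W
}

#' Downsample a fine optical volume to the network target tensor
#'
#' Fine z slices are averaged into coarse slabs, then each slab is resampled
#' in-plane by bicubic (Catmull-Rom) interpolation at the coarse voxel
#' centers of the scan region, producing the (16 x 16 x 8 x 2) target with
#' channels (mu_a, mu_s'); trilinear in-plane resampling is available as an
#' alternative.
#'
#' @param volume list with `mua`, `musp` arrays on the fine grid.
#' @param geometry a [volume_geometry()].
#' @param method `"bicubic"` (default) or `"trilinear"`.
#' @return numeric array (nx x ny x nz x 2) on the coarse target grid.
#' @export
prepare_target <- function(volume, geometry = volume_geometry(),
                           method = c("bicubic", "trilinear")) {
  method <- match.arg(method)
  d <- geometry$fine_dim
  stopifnot(all(dim(volume$mua) == d))
  tg <- coarse_target_grid(geometry)
  ratio <- geometry$coarse_spacing_mm / geometry$fine_spacing_mm
  stopifnot(abs(ratio - round(ratio)) < 1e-9)
  ratio <- as.integer(round(ratio))
  ctr <- grid_centers(tg)
  fx <- fine_centers(geometry, 1); fy <- fine_centers(geometry, 2)
  Wx <- interp_matrix_1d(fx, ctr$x, method)
  Wy <- interp_matrix_1d(fy, ctr$y, method)
  out <- array(0, c(tg$dim, 2L))
  for (ch in 1:2) {
    arr <- if (ch == 1) volume$mua else volume$musp
    for (k in seq_len(tg$dim[3])) {
      fine_k <- (k - 1L) * ratio + seq_len(ratio)
      slab <- arr[, , fine_k[1]]
      if (ratio > 1) {
        for (m in 2:ratio) slab <- slab + arr[, , fine_k[m]]
        slab <- slab / ratio
      }
      out[, , k, ch] <- Wx %*% slab %*% t(Wy)
    }
  }
  out
}
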