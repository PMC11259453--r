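#' Simulate a linescan acquisition
#'
#' Runs one frequency-domain diffusion solve per probe position (all
#' positions share a single operator factorization) and samples the complex
#' fluence at the detector locations.  Channels are packed per the protocol
#' table: all natural-log amplitude channels first, then all phase channels
#' in degrees (phase lag positive), position-major with detectors innermost.
#'
#' @param volume list with `mua`, `musp` arrays on the fine grid of the
#'   protocol's geometry.
#' @param protocol a [build_scan_protocol()].
#' @param config a [fd_solver_config()].
#' @param precond optional [solver_context()] reused as preconditioner
#'   (e.g. built once for a homogeneous reference background).
#' @return an object of class `"measurement_set"`.
#' @export
simulate_scan <- function(volume, protocol, config = fd_solver_config(),
                          precond = NULL) {
  stopifnot(inherits(protocol, "scan_protocol"))
  geometry <- protocol$geometry
  d <- geometry$fine_dim
  stopifnot(all(dim(volume$mua) == d))
  # local source depth rule: 1/mu_s' of the surface cell under the source
  src <- t(vapply(seq_len(protocol$n_positions), function(p) {
    xy <- protocol$positions[p, ]
    dw <- detector_weights(xy, geometry)
    musp_loc <- sum(volume$musp[dw$index] * dw$weight)
    source_point(xy, musp_loc)
  }, numeric(3)))
  phi <- solve_fd_diffusion(volume, src, geometry, config, precond = precond)
  m <- matrix(0 + 0i, protocol$n_positions, protocol$probe$n_detectors)
  for (p in seq_len(protocol$n_positions)) {
    for (dt in seq_len(protocol$probe$n_detectors)) {
      xy <- protocol$positions[p, ] + c(protocol$probe$detector_offsets_mm[dt], 0)
      dw <- detector_weights(xy, geometry)
      m[p, dt] <- sum(phi[dw$index, p] * dw$weight)
    }
  }
  pack_measurements(as.vector(t(m)), protocol,
                    iterations = attr(phi, "iterations"))
}

# pack complex pair readings (ordered position-major, detectors inner) into
# the channel layout: log_e amplitude block then phase (degrees) block
pack_measurements <- function(cmplx, protocol, iterations = NA_integer_) {
  logamp <- log(Mod(cmplx))
  phase <- -(180 / pi) * Arg(cmplx)
  if (any(!is.finite(logamp)) || any(!is.finite(phase)))
    stop("non-finite boundary measurement")
  if (any(abs(phase) >= 180))
    stop("phase outside (-180, 180]: unwrapping convention violated")
  structure(list(values = c(logamp, phase),
                 noise_applied = FALSE,
                 protocol_hash = protocol$hash,
                 n_channels = protocol$n_channels,
                 solver_iterations = iterations),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  n <- x$n_channels
  cat(sprintf("FD-DOT measurement set: %d channels (%d log-amplitude + %d phase)%s\n",
              n, n / 2, n / 2, if (x$noise_applied) ", noise applied" else ""))
  cat(sprintf("  log-amplitude range [%.3f, %.3f], phase range [%.2f, %.2f] deg\n",
              min(x$values[1:(n / 2)]), max(x$values[1:(n / 2)]),
              min(x$values[(n / 2 + 1):n]), max(x$values[(n / 2 + 1):n])))
  invisible(x)
}

#' Helper: split a measurement vector into amplitude and phase blocks
#' @param meas a `"measurement_set"` or numeric vector.
#' @return list `logamp`, `phase`.
#' @export
measurement_blocks <- function(meas) {
  v <- if (inherits(meas, "measurement_set")) meas$values else meas
  n <- length(v)
  list(logamp = v[seq_len(n / 2)], phase = v[(n / 2 + 1):n])
}

#' Amplitude-dependent measurement noise model
#'
#' A two-parameter stand-in for a system-derived noise model: the AC
#' amplitude receives multiplicative Gaussian noise (equivalently additive
#' in log-amplitude) whose relative standard deviation is a proportional
#' term plus an additive floor expressed relative to the brightest channel
#' of the scan; the phase receives additive Gaussian noise whose standard
#' deviation interpolates between `phase_sd_min_deg` at the brightest
#' channel and `phase_sd_max_deg` at the dimmest (log-amplitude linear), so
#' longer source-detector separations are noisier.
#'
#' @param amplitude_proportional_sd relative sd of AC amplitude.
#' @param amplitude_floor_frac noise floor as a fraction of the maximum
#'   amplitude in the scan.
#' @param phase_sd_min_deg,phase_sd_max_deg phase sd bounds (degrees).
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(amplitude_proportional_sd = 0.01,
                        amplitude_floor_frac = 1e-4,
                        phase_sd_min_deg = 0.2,
                        phase_sd_max_deg = 1.0) {
  stopifnot(amplitude_proportional_sd >= 0, amplitude_floor_frac >= 0,
            phase_sd_min_deg >= 0, phase_sd_max_deg >= phase_sd_min_deg)
  structure(list(amplitude_proportional_sd = amplitude_proportional_sd,
                 amplitude_floor_frac = amplitude_floor_frac,
                 phase_sd_min_deg = phase_sd_min_deg,
                 phase_sd_max_deg = phase_sd_max_deg),
            class = "noise_model")
}

#' Per-channel noise standard deviations for a measurement set
#' @param meas a `"measurement_set"` (noise-free).
#' @param model a [noise_model()].
#' @return list `logamp_sd`, `phase_sd_deg`.
#' @export
noise_sd <- function(meas, model) {
  b <- measurement_blocks(meas)
  a_rel <- b$logamp - max(b$logamp)          # log amplitude relative to peak
  rel_sd <- sqrt(model$amplitude_proportional_sd^2 +
                 (model$amplitude_floor_frac * exp(-a_rel))^2)
  rng <- max(b$logamp) - min(b$logamp)
  t <- if (rng > 0) (max(b$logamp) - b$logamp) / rng else rep(0, length(b$logamp))
  phase_sd <- model$phase_sd_min_deg +
    t * (model$phase_sd_max_deg - model$phase_sd_min_deg)
  list(logamp_sd = rel_sd, phase_sd_deg = phase_sd)
}

#' Add measurement noise
#'
#' @param meas a noise-free `"measurement_set"`.
#' @param model a [noise_model()].
#' @param seed integer seed; deterministic per seed.
#' @return a `"measurement_set"` with `noise_applied = TRUE`.
#' @export
add_noise <- function(meas, model = noise_model(), seed = NULL) {
  stopifnot(inherits(meas, "measurement_set"))
  if (meas$noise_applied) stop("noise already applied to this measurement set")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  b <- measurement_blocks(meas)
  sds <- noise_sd(meas, model)
  out <- meas
  out$values <- c(b$logamp + stats::rnorm(length(b$logamp), 0, sds$logamp_sd),
                  b$phase + stats::rnorm(length(b$phase), 0, sds$phase_sd_deg))
  out$noise_applied <- TRUE
  out
}
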