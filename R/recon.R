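#' Configuration of the model-based iterative reconstruction
#'
#' Levenberg-Marquardt/Tikhonov inversion in the under-determined form
#' \eqn{\delta\mu = J^T (J J^T + \lambda I)^{-1} \delta\Phi}, with the
#' regularization initialized at `lambda_init_factor` times the maximum
#' diagonal of \eqn{JJ^T} (computed on the normalized system) and decayed by
#' `lambda_decay` each iteration; iteration stops when the relative
#' projection-error improvement falls below `convergence_threshold`.  Each
#' parameter's update image is Gaussian-smoothed before application, and the
#' estimate is clamped positive.
#'
#' @param lambda_init_factor initial lambda as a fraction of
#'   `max(diag(JJ^T))`.
#' @param lambda_decay decay factor per iteration (> 1).
#' @param convergence_threshold relative projection-error improvement below
#'   which iteration stops.
#' @param smoothing_fwhm_mm Gaussian FWHM per axis applied to each update.
#' @param max_iterations iteration cap.
#' @param recon_fine_spacing_mm spacing of the reconstruction solve grid
#'   (distinct from the simulation grid to avoid inverse crime).
#' @param positivity_floor_frac positivity clamp, as a fraction of the
#'   initial background value of each parameter.
#' @return an object of class `"fem_recon_config"`.
#' @export
fem_recon_config <- function(lambda_init_factor = 0.01,
                             lambda_decay = 10^0.25,
                             convergence_threshold = 0.02,
                             smoothing_fwhm_mm = c(8, 8, 8),
                             max_iterations = 25L,
                             recon_fine_spacing_mm = 4,
                             positivity_floor_frac = 0.1) {
  stopifnot(lambda_init_factor > 0, lambda_decay > 1,
            convergence_threshold > 0, convergence_threshold < 1,
            length(smoothing_fwhm_mm) == 3, all(smoothing_fwhm_mm >= 0),
            max_iterations >= 1)
  structure(list(lambda_init_factor = lambda_init_factor,
                 lambda_decay = lambda_decay,
                 convergence_threshold = convergence_threshold,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 max_iterations = as.integer(max_iterations),
                 recon_fine_spacing_mm = recon_fine_spacing_mm,
                 positivity_floor_frac = positivity_floor_frac),
            class = "fem_recon_config")
}

#' Row- and column-normalize the linearized system
#'
#' Rows are scaled by the magnitude of the corresponding measured datum
#' (log-amplitude and phase blocks carry their own dynamic ranges), columns
#' by the current voxel optical-property values, so that the regularized
#' inversion sees dimensionless quantities; the returned scales map the
#' normalized update back to physical units.
#'
#' @param J sensitivity matrix (n x m).
#' @param residual data residual (length n).
#' @param measured measured data vector (length n) supplying the row scales.
#' @param estimate current estimate vector (length m) supplying the column
#'   scales.
#' @return list `J`, `residual`, `row_scales`, `col_scales`.
#' @export
normalize_system <- function(J, residual, measured, estimate) {
  stopifnot(nrow(J) == length(residual), length(measured) == nrow(J),
            ncol(J) == length(estimate))
  rs <- abs(measured)
  if (any(rs == 0))
    stop(sprintf("zero row scale at channel %d", which(rs == 0)[1]))
  cs <- abs(estimate)
  if (any(cs == 0))
    stop(sprintf("zero column scale at basis entry %d", which(cs == 0)[1]))
  list(J = sweep(sweep(J, 1, rs, `/`), 2, cs, `*`),
       residual = residual / rs,
       row_scales = rs, col_scales = cs)
}

#' One regularized under-determined update
#'
#' \eqn{\delta\mu = J^T (J J^T + \lambda I)^{-1} \delta\Phi}, solved through
#' a symmetric positive-definite factorization of the n x n system.
#'
#' @param J sensitivity matrix (n x m).
#' @param delta_phi data residual (length n).
#' @param lambda regularization (> 0).
#' @return update vector delta-mu (length m).
#' @export
update_step <- function(J, delta_phi, lambda) {
  stopifnot(lambda > 0, nrow(J) == length(delta_phi))
  JJt <- tcrossprod(J)
  diag(JJt) <- diag(JJt) + lambda
  ch <- tryCatch(chol(JJt), error = function(e)
    stop(sprintf("normal-equations factorization failed at lambda = %g: %s",
                 lambda, conditionMessage(e))))
  as.vector(crossprod(J, backsolve(ch, forwardsolve(t(ch), delta_phi))))
}

#' Separable 3D Gaussian smoothing
#'
#' @param arr 3D array.
#' @param fwhm_mm Gaussian FWHM per axis (mm).
#' @param spacing_mm voxel spacing (mm).
#' @param truncate kernel truncation in standard deviations.
#' @return smoothed array (kernel renormalized at the edges).
#' @export
gauss_smooth3d <- function(arr, fwhm_mm, spacing_mm, truncate = 3) {
  d <- dim(arr)
  for (ax in 1:3) {
    if (fwhm_mm[ax] <= 0) next
    sig <- fwhm_mm[ax] / (2 * sqrt(2 * log(2))) / spacing_mm
    half <- max(1L, as.integer(ceiling(truncate * sig)))
    k <- exp(-0.5 * ((-half:half) / sig)^2)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# 1D convolution along an axis with edge renormalization
convolve_axis <- function(arr, kernel, ax) {
  d <- dim(arr)
  half <- (length(kernel) - 1L) / 2L
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- dim(a)[1]
  mat <- matrix(a, nrow = m)
  out <- matrix(0, nrow = m, ncol = ncol(mat))
  wt <- numeric(m)
  for (o in -half:half) {
    src <- seq_len(m) + o
    ok <- src >= 1 & src <= m
    w <- kernel[o + half + 1L]
    out[ok, ] <- out[ok, ] + w * mat[src[ok], ]
    wt[ok] <- wt[ok] + w
  }
  out <- out / wt
  aperm(array(out, dim(a)), order(perm))
}

#' Model-based iterative DOT reconstruction
#'
#' Reconstructs absorption and reduced scattering on the coarse target basis
#' from one measurement set: at each iteration the forward model is solved
#' on the reconstruction grid at the current estimate, the Jacobian is
#' recomputed by the adjoint method, the system is row/column-normalized,
#' the Tikhonov update is computed and Gaussian-smoothed per parameter, the
#' estimate updated and clamped positive, and lambda decayed.  Iteration
#' stops when the projection error improves by less than the convergence
#' threshold, at the iteration cap, or (with a warning) after three
#' consecutive diverging iterations.
#'
#' @param measurements a `"measurement_set"`.
#' @param protocol the [build_scan_protocol()] the data were acquired with.
#' @param config a [fem_recon_config()].
#' @param solver_config a [fd_solver_config()].
#' @param initial_background length-2 (mua, musp) homogeneous initial
#'   estimate; defaults to the canonical dataset background means.
#' @return an object of class `"dot_recon"`: `mua`, `musp` on the coarse
#'   target grid, `history` (per-iteration lambda, projection error, update
#'   norm), `iterations`, `converged`, `elapsed_s`, `method = "fem"`.
#' @export
dot_reconstruct <- function(measurements, protocol,
                            config = fem_recon_config(),
                            solver_config = fd_solver_config(),
                            initial_background = c(0.005, 0.98)) {
  stopifnot(inherits(measurements, "measurement_set"),
            inherits(protocol, "scan_protocol"))
  if (!identical(measurements$protocol_hash, protocol$hash))
    stop("measurement set was not acquired with this protocol")
  stopifnot(all(initial_background > 0))
  t0 <- proc.time()[3]
  g0 <- protocol$geometry
  # the reconstruction solve grid may not divide the simulation extents
  # exactly; the volume is truncated to the largest contained multiple
  # (only ever trims the deep boundary, far below the sensitive region)
  rext <- floor(g0$extent_mm / config$recon_fine_spacing_mm) *
    config$recon_fine_spacing_mm
  rg <- volume_geometry(extent_mm = rext,
                        fine_spacing_mm = config$recon_fine_spacing_mm,
                        coarse_spacing_mm = g0$coarse_spacing_mm,
                        scan_region_mm = g0$scan_region_mm,
                        target_depth_mm = g0$target_depth_mm)
  tg <- coarse_target_grid(rg)
  est <- list(mua = array(initial_background[1], tg$dim),
              musp = array(initial_background[2], tg$dim))
  floor_vals <- config$positivity_floor_frac * initial_background
  measured <- measurements$values
  history <- data.frame(iteration = integer(), lambda = numeric(),
                        projection_error = numeric(), update_norm = numeric())
  lambda <- NA_real_
  prev_err <- Inf; n_div <- 0L; converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    fine <- prolong_estimate(est, rg, initial_background)
    jac <- fd_jacobian(fine, protocol, solver_config, geometry = rg)
    residual <- measured - jac$modeled$values
    err <- sqrt(sum(residual^2))
    if (is.finite(prev_err)) {
      improve <- if (prev_err > 0) (prev_err - err) / prev_err else 0
      if (improve < 0) {
        n_div <- n_div + 1L
        if (n_div >= 3L) {
          warning(sprintf(
            "projection error diverging for 3 consecutive iterations (%.4g -> %.4g); aborting",
            prev_err, err))
          break
        }
      } else {
        n_div <- 0L
        if (improve < config$convergence_threshold) { converged <- TRUE; break }
      }
    }
    est_vec <- c(as.vector(est$mua), as.vector(est$musp))
    ns <- normalize_system(jac$J, residual, measured, est_vec)
    if (it == 1L) {
      jjt_diag <- rowSums(ns$J^2)
      lambda <- config$lambda_init_factor * max(jjt_diag)
    }
    dmu_n <- update_step(ns$J, ns$residual, lambda)
    dmu <- dmu_n * ns$col_scales
    nb <- prod(tg$dim)
    d_mua <- gauss_smooth3d(array(dmu[seq_len(nb)], tg$dim),
                            config$smoothing_fwhm_mm, tg$spacing)
    d_musp <- gauss_smooth3d(array(dmu[nb + seq_len(nb)], tg$dim),
                             config$smoothing_fwhm_mm, tg$spacing)
    est$mua <- pmax(est$mua + d_mua, floor_vals[1])
    est$musp <- pmax(est$musp + d_musp, floor_vals[2])
    history <- rbind(history, data.frame(
      iteration = it, lambda = lambda, projection_error = err,
      update_norm = sqrt(sum(dmu^2))))
    prev_err <- err
    lambda <- lambda / config$lambda_decay
  }
  structure(list(mua = est$mua, musp = est$musp, grid = tg,
                 history = history, iterations = nrow(history),
                 converged = converged,
                 residual = residual,
                 elapsed_s = proc.time()[3] - t0,
                 method = "fem", config = config),
            class = "dot_recon")
}

#' @export
print.dot_recon <- function(x, ...) {
  cat(sprintf("DOT reconstruction (%s), %d x %d x %d basis\n",
              x$method, x$grid$dim[1], x$grid$dim[2], x$grid$dim[3]))
  cat(sprintf("  %d iterations, %s, %.2f s\n", x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$elapsed_s))
  cat(sprintf("  mua  range [%.5f, %.5f] mm^-1\n", min(x$mua), max(x$mua)))
  cat(sprintf("  musp range [%.4f, %.4f] mm^-1\n", min(x$musp), max(x$musp)))
  invisible(x)
}

#' @export
summary.dot_recon <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("  iteration history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.dot_recon <- function(x, z = NULL, parameter = c("mua", "musp"), ...) {
  parameter <- match.arg(parameter)
  vol <- x[[parameter]]
  if (is.null(z)) z <- ceiling(dim(vol)[3] / 2)
  graphics::image(vol[, , z], useRaster = TRUE, asp = 1,
                  main = sprintf("%s, slice z = %d (%s)", parameter, z, x$method),
                  ...)
  invisible(x)
}

#' @export
coef.dot_recon <- function(object, ...) {
  list(mua = object$mua, musp = object$musp)
}

#' Data-space residuals of a reconstruction
#'
#' The misfit between the measured data and the forward model at the final
#' estimate (log-amplitude block then phase block, degrees).
#' @param object a `"dot_recon"`.
#' @param ... unused.
#' @export
residuals.dot_recon <- function(object, ...) object$residual

#' Calibrate the initial regularization factor on validation volumes
#'
#' Reconstructs a small set of validation examples at each candidate
#' `lambda_init_factor` (a logarithmic grid by default) and selects the
#' factor minimizing the mean background-relative RMSE over both parameters;
#' a single factor is then used for every test reconstruction, mirroring
#' validation-based selection of the regularization level.
#'
#' @param examples list of validation examples, each with `measurements` (a
#'   `"measurement_set"`) and `volume` (truth rasterized on the target grid).
#' @param protocol the acquisition [build_scan_protocol()].
#' @param config base [fem_recon_config()]; all fields except the factor are
#'   kept.
#' @param solver_config a [fd_solver_config()].
#' @param factors candidate initial factors.
#' @param initial_background homogeneous initial estimate.
#' @return list with `factor` (the selected value), `table` (mean relative
#'   RMSE per candidate), and `config` (the base config with the selected
#'   factor filled in).
#' @export
calibrate_lambda_factor <- function(examples, protocol,
                                    config = fem_recon_config(),
                                    solver_config = fd_solver_config(),
                                    factors = 10^seq(-4, 0),
                                    initial_background = c(0.005, 0.98)) {
  stopifnot(length(examples) >= 1, length(factors) >= 1)
  score <- numeric(length(factors))
  for (fi in seq_along(factors)) {
    cfg <- config
    cfg$lambda_init_factor <- factors[fi]
    rel <- 0
    for (ex in examples) {
      r <- suppressWarnings(
        dot_reconstruct(ex$measurements, protocol, cfg, solver_config,
                        initial_background = initial_background))
      rel <- rel +
        sqrt(mean((r$mua - ex$volume$mua)^2)) / initial_background[1] +
        sqrt(mean((r$musp - ex$volume$musp)^2)) / initial_background[2]
    }
    score[fi] <- rel / (2 * length(examples))
  }
  best <- which.min(score)
  out_cfg <- config
  out_cfg$lambda_init_factor <- factors[best]
  list(factor = factors[best],
       table = data.frame(factor = factors, mean_relative_rmse = score),
       config = out_cfg)
}
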