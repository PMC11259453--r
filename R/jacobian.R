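#' Adjoint-method Jacobian of the boundary measurements
#'
#' Builds the sensitivity matrix of every log-amplitude and phase channel
#' with respect to the absorption and reduced-scattering value of every
#' coarse-basis voxel, by the adjoint method: one direct solve per probe
#' position and one adjoint solve per distinct detector location, with the
#' per-cell sensitivity assembled from the exact derivative of the discrete
#' finite-volume operator (absorption acts on the diagonal; the diffusion
#' coefficient acts through the harmonic-mean face conductances and the
#' Robin boundary term, and both optical parameters act on kappa through
#' kappa = 1/(3(mua + musp))).  Fine-cell sensitivities are aggregated onto
#' the coarse target basis; cells outside the target block are not unknowns.
#'
#' Row order matches the measurement layout (all log-amplitude rows, then
#' all phase rows in degrees); column order is all mu_a voxels then all
#' mu_s' voxels, column-major over the coarse grid.
#'
#' @param volume list with `mua`, `musp` arrays on the fine grid of
#'   `geometry` (typically the current coarse estimate prolonged with
#'   [prolong_estimate()]).
#' @param protocol a [build_scan_protocol()]; its positions are reused on
#'   `geometry`, which may be a coarser reconstruction grid than the
#'   protocol's own simulation grid.
#' @param config a [fd_solver_config()].
#' @param geometry the grid on which the solves are performed; defaults to
#'   the protocol's geometry.
#' @param precond optional [solver_context()] preconditioner.
#' @return list with `J` (n_channels x 2*n_coarse matrix), `modeled` (the
#'   model-predicted `"measurement_set"` at this volume, shared solves), and
#'   `n_basis`.
#' @export
fd_jacobian <- function(volume, protocol, config = fd_solver_config(),
                        geometry = protocol$geometry, precond = NULL) {
  d <- geometry$fine_dim; h <- geometry$fine_spacing_mm
  stopifnot(all(dim(volume$mua) == d))
  kap <- diffusion_coefficient(volume$mua, volume$musp)
  n <- prod(d)
  npos <- protocol$n_positions; ndet <- protocol$probe$n_detectors
  # distinct detector locations (shared across probe positions where arms
  # overlap on the scan lattice)
  det_xy <- do.call(rbind, lapply(seq_len(npos), function(p)
    cbind(protocol$positions[p, 1] + protocol$probe$detector_offsets_mm,
          protocol$positions[p, 2])))
  key <- paste(round(det_xy[, 1], 9), round(det_xy[, 2], 9))
  uniq <- !duplicated(key)
  det_id <- match(key, key[uniq])
  det_u <- det_xy[uniq, , drop = FALSE]
  # RHS block: sources then adjoint (detector) sources
  src <- t(vapply(seq_len(npos), function(p) {
    xy <- protocol$positions[p, ]
    dw <- detector_weights(xy, geometry)
    source_point(xy, sum(volume$musp[dw$index] * dw$weight))
  }, numeric(3)))
  B <- matrix(0 + 0i, n, npos + nrow(det_u))
  for (s in seq_len(npos)) {
    rhs <- point_source_rhs(src[s, ], geometry)
    B[rhs$index, s] <- B[rhs$index, s] + rhs$weight
  }
  det_w <- vector("list", nrow(det_u))
  for (dd in seq_len(nrow(det_u))) {
    dw <- detector_weights(det_u[dd, ], geometry)
    det_w[[dd]] <- dw
    B[dw$index, npos + dd] <- B[dw$index, npos + dd] + dw$weight
  }
  op <- build_diffusion_operator(volume, geometry, config)
  papply <- if (is.null(precond))
    make_preconditioner(op, if (prod(d) <= 25000) "direct" else "twogrid")
  else precond$papply
  X <- cocg_solve(op$K, op$sigma, B, papply, tol = config$tol,
                  maxit = config$maxit)$x
  phi_s <- X[, seq_len(npos), drop = FALSE]
  phi_d <- X[, npos + seq_len(nrow(det_u)), drop = FALSE]
  # modeled complex readings, position-major detectors inner
  model_c <- complex(npos * ndet)
  pair_src <- integer(npos * ndet); pair_det <- integer(npos * ndet)
  i <- 1L
  for (p in seq_len(npos)) for (dt in seq_len(ndet)) {
    dd <- det_id[(p - 1) * ndet + dt]
    dw <- det_w[[dd]]
    model_c[i] <- sum(phi_s[dw$index, p] * dw$weight)
    pair_src[i] <- p; pair_det[i] <- dd
    i <- i + 1L
  }
  # coarse-basis aggregation map (cached sparse operator per geometry)
  agg <- coarse_agg_matrix(geometry)
  nb <- agg$nb
  lin <- array(seq_len(n), d)
  # precompute face index pairs and conductance derivatives per axis
  faces <- lapply(1:3, function(ax) {
    idx_lo <- switch(ax, lin[-d[1], , ], lin[, -d[2], ], lin[, , -d[3]])
    idx_hi <- switch(ax, lin[-1, , ], lin[, -1, ], lin[, , -1])
    klo <- kap[idx_lo]; khi <- kap[idx_hi]
    list(lo = as.vector(idx_lo), hi = as.vector(idx_hi),
         dg_dklo = as.vector(2 * khi^2 / (klo + khi)^2) / h^2,
         dg_dkhi = as.vector(2 * klo^2 / (klo + khi)^2) / h^2)
  })
  bnd <- local({
    idx <- c(lin[1, , ], lin[d[1], , ], lin[, 1, ], lin[, d[2], ],
             lin[, , 1], lin[, , d[3]])
    kb <- kap[idx]
    alpha <- 2 * kb / h; beta <- 1 / (2 * config$boundary_A)
    list(idx = idx, dbdk = 2 * beta^2 / (h^2 * (alpha + beta)^2))
  })
  dkap <- as.numeric(-3 * kap^2)   # d kappa / d mua = d kappa / d musp
  npair <- npos * ndet
  Dmua <- matrix(0 + 0i, n, npair)
  Dmusp <- matrix(0 + 0i, n, npair)
  for (q in seq_len(npair)) {
    fs <- phi_s[, pair_src[q]]; fd_ <- phi_d[, pair_det[q]]
    c_kap <- numeric(n) + 0i
    for (ax in 1:3) {
      f <- faces[[ax]]
      ds <- (fs[f$lo] - fs[f$hi]) * (fd_[f$lo] - fd_[f$hi])
      c_kap[f$lo] <- c_kap[f$lo] + f$dg_dklo * ds
      c_kap[f$hi] <- c_kap[f$hi] + f$dg_dkhi * ds
    }
    c_kap[bnd$idx] <- c_kap[bnd$idx] + bnd$dbdk * fs[bnd$idx] * fd_[bnd$idx]
    dm_dkap <- -c_kap * dkap       # mapped through kappa to the parameters
    Dmusp[, q] <- dm_dkap
    Dmua[, q] <- -(fs * fd_) + dm_dkap
  }
  # aggregate fine-cell sensitivities onto the coarse basis: (nb x npair)
  amm <- function(M) {
    t(as.matrix(Matrix::crossprod(agg$A, Re(M))) +
        1i * as.matrix(Matrix::crossprod(agg$A, Im(M))))
  }
  Jc_mua <- amm(Dmua)
  Jc_musp <- amm(Dmusp)
  # complex rows -> log-amplitude and phase(degree) rows: d log m = dm / m
  inv_m <- 1 / model_c
  Jc <- cbind(Jc_mua, Jc_musp) * inv_m
  J <- rbind(Re(Jc), -(180 / pi) * Im(Jc))
  list(J = J,
       modeled = pack_measurements(model_c, protocol),
       n_basis = nb)
}

# sparse fine-cell -> coarse-voxel aggregation operator, memoized
.agg_cache <- new.env(parent = emptyenv())
coarse_agg_matrix <- function(geometry) {
  key <- paste(c(geometry$fine_dim, geometry$fine_spacing_mm,
                 geometry$coarse_spacing_mm), collapse = "|")
  got <- get0(key, envir = .agg_cache)
  if (!is.null(got)) return(got)
  cmap <- as.vector(fine_to_coarse_map(geometry))
  inb <- cmap > 0L
  nb <- max(cmap)
  A <- Matrix::sparseMatrix(i = which(inb), j = cmap[inb], x = 1,
                            dims = c(length(cmap), nb))
  out <- list(A = A, nb = nb)
  assign(key, out, envir = .agg_cache)
  out
}

#' Prolong a coarse-basis estimate onto a fine solve grid
#'
#' Piecewise-constant injection of the coarse target-block estimate into a
#' full-volume fine grid; cells outside the target block keep the supplied
#' background values.
#'
#' @param est list with `mua`, `musp` arrays on the coarse target grid.
#' @param geometry the solve-grid [volume_geometry()].
#' @param background length-2 numeric: background (mua, musp) outside the
#'   target block.
#' @return list with full fine-grid `mua`, `musp`.
#' @export
prolong_estimate <- function(est, geometry, background) {
  cmap <- fine_to_coarse_map(geometry)
  mua <- array(background[1], geometry$fine_dim)
  musp <- array(background[2], geometry$fine_dim)
  inb <- cmap > 0L
  mua[inb] <- est$mua[cmap[inb]]
  musp[inb] <- est$musp[cmap[inb]]
  list(mua = mua, musp = musp)
}
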