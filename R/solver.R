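#' Frequency-domain diffusion solver configuration
#'
#' Physics constants for the forward model: the source modulation frequency,
#' the tissue refractive index (fixing the speed of light in the medium),
#' and the Robin boundary-condition reflection parameter `A`.  When `A` is
#' `NULL` it is computed from the refractive index with the standard
#' polynomial internal-reflection approximation.  The collimated source is
#' modeled as an isotropic point at depth 1/mu_s' below the surface.
#'
#' @param modulation_frequency_Hz source modulation frequency (Hz).
#' @param refractive_index tissue refractive index (>= 1).
#' @param boundary_A Robin boundary reflection parameter; `NULL` for the
#'   Fresnel-based approximation.
#' @param tol relative residual tolerance of the iterative linear solver.
#' @param maxit iteration cap of the linear solver.
#' @return an object of class `"fd_solver_config"`.
#' @export
fd_solver_config <- function(modulation_frequency_Hz = 140e6,
                             refractive_index = 1.33,
                             boundary_A = NULL,
                             tol = 1e-7, maxit = 400L) {
  stopifnot(modulation_frequency_Hz >= 0, refractive_index >= 1,
            tol > 0, maxit > 0)
  c0 <- 2.99792458e11  # mm/s
  n <- refractive_index
  if (is.null(boundary_A)) {
    r_eff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
    boundary_A <- (1 + r_eff) / (1 - r_eff)
  }
  structure(list(modulation_frequency_Hz = modulation_frequency_Hz,
                 refractive_index = n,
                 c_medium_mm_s = c0 / n,
                 omega = 2 * pi * modulation_frequency_Hz,
                 boundary_A = boundary_A,
                 tol = tol, maxit = as.integer(maxit)),
            class = "fd_solver_config")
}

# diffusion coefficient field kappa = 1/(3(mua + musp)), mm
diffusion_coefficient <- function(mua, musp) 1 / (3 * (mua + musp))

#' Assemble the discrete frequency-domain diffusion operator
#'
#' Cell-centered finite-volume discretization of
#' \eqn{-\nabla\cdot(\kappa\nabla\Phi) + (\mu_a + i\omega/c)\Phi = q}
#' with harmonic-mean face diffusivities and the Robin boundary condition
#' \eqn{\Phi + 2A\kappa\,\partial\Phi/\partial n = 0} on all faces.  The
#' operator is returned in per-volume form as its real SPD part `K` (a
#' sparse `dgCMatrix`) plus the constant imaginary diagonal shift
#' `sigma = omega / c`.
#'
#' @param volume list with 3D arrays `mua`, `musp` on the fine grid.
#' @param geometry a [volume_geometry()].
#' @param config a [fd_solver_config()].
#' @return list `K`, `sigma`, `dim`, `h`, plus the `kappa` array.
#' @export
build_diffusion_operator <- function(volume, geometry, config = fd_solver_config()) {
  d <- if (inherits(geometry, "volume_geometry")) geometry$fine_dim else geometry$dim
  h <- if (inherits(geometry, "volume_geometry")) geometry$fine_spacing_mm
       else geometry$spacing
  stopifnot(all(dim(volume$mua) == d), all(dim(volume$musp) == d))
  if (any(volume$mua <= 0) || any(volume$musp <= 0))
    stop("optical properties must be strictly positive")
  kap <- diffusion_coefficient(volume$mua, volume$musp)
  n <- prod(d)
  lin <- array(seq_len(n), d)
  diag_acc <- as.numeric(volume$mua)
  xx <- vector("list", 3)
  for (ax in 1:3) {
    # interior faces along axis ax: between index m and m+1
    idx_lo <- switch(ax,
                     lin[-d[1], , , drop = FALSE],
                     lin[, -d[2], , drop = FALSE],
                     lin[, , -d[3], drop = FALSE])
    idx_hi <- switch(ax,
                     lin[-1, , , drop = FALSE],
                     lin[, -1, , drop = FALSE],
                     lin[, , -1, drop = FALSE])
    klo <- kap[idx_lo]; khi <- kap[idx_hi]
    g <- 2 * klo * khi / (klo + khi) / h^2   # face conductance, per volume
    xx[[ax]] <- c(-g, -g)
    dacc <- numeric(n)
    dacc[idx_lo] <- dacc[idx_lo] + g
    dacc2 <- numeric(n); dacc2[idx_hi] <- dacc2[idx_hi] + g
    diag_acc <- diag_acc + dacc + dacc2
    # boundary faces at both ends of axis ax
    for (end in c(1L, 2L)) {
      idx_b <- switch(ax,
                      if (end == 1L) lin[1, , ] else lin[d[1], , ],
                      if (end == 1L) lin[, 1, ] else lin[, d[2], ],
                      if (end == 1L) lin[, , 1] else lin[, , d[3]])
      kb <- kap[idx_b]
      alpha <- 2 * kb / h
      beta <- 1 / (2 * config$boundary_A)
      bterm <- (alpha * beta / (alpha + beta)) / h
      dacc <- numeric(n); dacc[idx_b] <- bterm
      diag_acc <- diag_acc + dacc
    }
  }
  K <- assemble_cached(d, c(diag_acc, unlist(xx)))
  list(K = K, sigma = config$omega / config$c_medium_mm_s,
       dim = d, h = h, kappa = kap,
       mua = as.numeric(volume$mua), musp = as.numeric(volume$musp),
       boundary_A = config$boundary_A)
}

# package-local cache of the 7-point sparsity pattern per grid shape: the
# triplet order is deterministic, so repeated assemblies on the same grid
# only refill the value slot of a cached dgCMatrix skeleton
.op_cache <- new.env(parent = emptyenv())

assemble_cached <- function(d, xvals) {
  key <- paste(d, collapse = "x")
  entry <- get0(key, envir = .op_cache)
  if (is.null(entry)) {
    n <- prod(d)
    lin <- array(seq_len(n), d)
    ii <- jj <- vector("list", 3)
    for (ax in 1:3) {
      idx_lo <- switch(ax, lin[-d[1], , ], lin[, -d[2], ], lin[, , -d[3]])
      idx_hi <- switch(ax, lin[-1, , ], lin[, -1, ], lin[, , -1])
      ii[[ax]] <- c(idx_lo, idx_hi)
      jj[[ax]] <- c(idx_hi, idx_lo)
    }
    i <- c(seq_len(n), unlist(ii)); j <- c(seq_len(n), unlist(jj))
    ord <- order(j, i)    # CSC slot order (no duplicate entries by design)
    skel <- Matrix::sparseMatrix(i = i[ord], j = j[ord],
                                 x = numeric(length(i)), dims = c(n, n))
    entry <- list(ord = ord, skel = skel)
    assign(key, entry, envir = .op_cache)
  }
  K <- entry$skel
  K@x <- xvals[entry$ord]
  K
}

#' Reusable solver context (operator + preconditioner)
#'
#' Builds the discrete operator for a volume and a Cholesky factorization of
#' its real part, used as the preconditioner of the conjugate-orthogonal CG
#' iteration.  A context built for one (e.g. homogeneous background) volume
#' can precondition solves for other volumes of similar optical properties:
#' pass it as `precond` to [solve_fd_diffusion()] or [simulate_scan()].
#'
#' @param volume list with `mua`, `musp` arrays on the fine grid.
#' @param geometry a [volume_geometry()].
#' @param config a [fd_solver_config()].
#' @return an object of class `"fd_solver_context"`.
#' @export
solver_context <- function(volume, geometry, config = fd_solver_config(),
                           type = c("auto", "direct", "twogrid")) {
  type <- match.arg(type)
  op <- build_diffusion_operator(volume, geometry, config)
  if (type == "auto") type <- if (prod(op$dim) <= 25000) "direct" else "twogrid"
  papply <- make_preconditioner(op, type)
  structure(list(op = op, papply = papply, type = type,
                 geometry = geometry, config = config),
            class = "fd_solver_context")
}

# Preconditioner closures mapping a complex residual block to an approximate
# solution of K z = r.  "direct": supernodal Cholesky of K.  "twogrid": one
# symmetric V(1,1) cycle -- damped-Jacobi smoothing around a coarse-level
# (2x spacing) correction solved by Cholesky; cheap enough to apply every
# iteration on large grids where factoring K itself dominates runtime.
make_preconditioner <- function(op, type) {
  if (type == "direct") {
    ch <- Matrix::Cholesky(op$K, LDL = FALSE, super = TRUE)
    function(R) {
      k <- ncol(R)
      S <- as.matrix(Matrix::solve(ch, cbind(Re(R), Im(R)), system = "A"))
      S[, seq_len(k), drop = FALSE] + 1i * S[, k + seq_len(k), drop = FALSE]
    }
  } else {
    d <- op$dim
    dc <- as.integer(ceiling(d / 2))
    parent_ax <- lapply(1:3, function(ax)
      pmin((seq_len(d[ax]) + 1L) %/% 2L, dc[ax]))
    parent <- as.vector(outer(outer(parent_ax[[1]],
                                    (parent_ax[[2]] - 1L) * dc[1], "+"),
                              (parent_ax[[3]] - 1L) * dc[1] * dc[2], "+"))
    nc <- prod(dc)
    P <- Matrix::sparseMatrix(i = seq_len(prod(d)), j = parent, x = 1,
                              dims = c(prod(d), nc))
    cnt <- Matrix::colSums(P)
    # coarse-level operator from child-averaged coefficients
    avg <- function(v) as.vector((Matrix::crossprod(P, v)) / cnt)
    vol_c <- list(mua = array(avg(op$mua), dc),
                  musp = array(avg(op$musp), dc))
    opc <- build_diffusion_operator(vol_c, list(dim = dc, spacing = 2 * op$h),
                                    list(boundary_A = op$boundary_A,
                                         omega = 0, c_medium_mm_s = 1))
    chc <- Matrix::Cholesky(opc$K, LDL = FALSE, super = TRUE)
    dinv <- 1 / Matrix::diag(op$K)
    omega_j <- 0.8
    K <- op$K
    csolve <- function(R) {
      k <- ncol(R)
      S <- as.matrix(Matrix::solve(chc, cbind(Re(R), Im(R)), system = "A"))
      S[, seq_len(k), drop = FALSE] + 1i * S[, k + seq_len(k), drop = FALSE]
    }
    kmul <- function(Z) {
      as.matrix(K %*% Re(Z)) + 1i * as.matrix(K %*% Im(Z))
    }
    pmul <- function(Z)
      as.matrix(P %*% Re(Z)) + 1i * as.matrix(P %*% Im(Z))
    ptmul <- function(Z)
      as.matrix(Matrix::crossprod(P, Re(Z))) +
        1i * as.matrix(Matrix::crossprod(P, Im(Z)))
    function(R) {
      z <- omega_j * dinv * R
      r2 <- R - kmul(z)
      z <- z + pmul(csolve(ptmul(r2)))
      r3 <- R - kmul(z)
      z + omega_j * dinv * r3
    }
  }
}

# preconditioned conjugate-orthogonal CG for the complex-symmetric system
# (K + i sigma I) X = B, preconditioner M ~ K_ref (real SPD factor).
# B: complex matrix n x k; returns list(x, iterations)
cocg_solve <- function(K, sigma, B, papply, tol = 1e-7, maxit = 400L) {
  cocg_core(K, sigma, B, papply, tol, as.integer(maxit))
}

# trilinear deposit of a unit point source at (x, y, z) onto cell centers;
# returns sparse RHS in per-volume form (so weights sum to 1/h^3)
point_source_rhs <- function(pt, geometry) {
  d <- geometry$fine_dim; h <- geometry$fine_spacing_mm
  u <- pt / h + 0.5              # fractional 1-based cell-center index
  i0 <- pmin(pmax(floor(u), 1), d)
  i1 <- pmin(i0 + 1, d)
  f <- pmin(pmax(u - i0, 0), 1)
  idx <- integer(8); w <- numeric(8); m <- 1L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- if (dx == 0) i0[1] else i1[1]
    iy <- if (dy == 0) i0[2] else i1[2]
    iz <- if (dz == 0) i0[3] else i1[3]
    wt <- (if (dx == 0) 1 - f[1] else f[1]) *
          (if (dy == 0) 1 - f[2] else f[2]) *
          (if (dz == 0) 1 - f[3] else f[3])
    idx[m] <- (iz - 1) * d[1] * d[2] + (iy - 1) * d[1] + ix
    w[m] <- wt
    m <- m + 1L
  }
  keep <- w > 0
  list(index = idx[keep], weight = w[keep] / h^3)
}

#' Detector sampling weights on the surface layer
#'
#' Bilinear interpolation weights that read the fluence at a surface
#' position (x, y) from the first cell layer of the fine grid; the same
#' functional defines the adjoint source of that detector.
#'
#' @param xy surface position (x, y) in mm.
#' @param geometry a [volume_geometry()].
#' @return list `index` (linear fine-grid indices), `weight`.
#' @export
detector_weights <- function(xy, geometry) {
  d <- geometry$fine_dim; h <- geometry$fine_spacing_mm
  u <- xy / h + 0.5
  i0 <- pmin(pmax(floor(u), 1), d[1:2])
  i1 <- pmin(i0 + 1, d[1:2])
  f <- pmin(pmax(u - i0, 0), 1)
  idx <- integer(4); w <- numeric(4); m <- 1L
  for (dy in 0:1) for (dx in 0:1) {
    ix <- if (dx == 0) i0[1] else i1[1]
    iy <- if (dy == 0) i0[2] else i1[2]
    wt <- (if (dx == 0) 1 - f[1] else f[1]) * (if (dy == 0) 1 - f[2] else f[2])
    idx[m] <- (iy - 1) * d[1] + ix   # z layer 1
    w[m] <- wt
    m <- m + 1L
  }
  keep <- w > 0
  list(index = idx[keep], weight = w[keep])
}

#' Solve the frequency-domain diffusion equation for point sources
#'
#' @param volume list with `mua`, `musp` arrays on the fine grid of
#'   `geometry`.
#' @param source_locations numeric matrix (k x 3) of source points in mm, or
#'   a single length-3 vector.  Use [source_point()] to apply the
#'   1/mu_s'-depth rule to a surface position.
#' @param geometry a [volume_geometry()].
#' @param config a [fd_solver_config()].
#' @param precond optional [solver_context()] supplying the preconditioner;
#'   by default a context is built from `volume` itself.
#' @return complex matrix (n_cells x k) of fluence fields; attribute
#'   `iterations` records the solver iteration count.
#' @export
solve_fd_diffusion <- function(volume, source_locations,
                               geometry = volume_geometry(),
                               config = fd_solver_config(),
                               precond = NULL) {
  if (is.null(dim(source_locations)))
    source_locations <- matrix(source_locations, nrow = 1)
  op <- if (!is.null(precond) && identical_volume(precond, volume)) precond$op
        else build_diffusion_operator(volume, geometry, config)
  papply <- if (is.null(precond)) {
    make_preconditioner(op, if (prod(op$dim) <= 25000) "direct" else "twogrid")
  } else precond$papply
  n <- prod(geometry$fine_dim)
  B <- matrix(0 + 0i, n, nrow(source_locations))
  for (s in seq_len(nrow(source_locations))) {
    rhs <- point_source_rhs(source_locations[s, ], geometry)
    B[rhs$index, s] <- B[rhs$index, s] + rhs$weight
  }
  sol <- cocg_solve(op$K, op$sigma, B, papply, tol = config$tol, maxit = config$maxit)
  out <- sol$x
  attr(out, "iterations") <- sol$iterations
  out
}

identical_volume <- function(ctx, volume) {
  isTRUE(all.equal(ctx$op$kappa, diffusion_coefficient(volume$mua, volume$musp),
                   tolerance = 1e-12))
}

#' Source point under a surface probe position
#'
#' Applies the collimated-source rule: an isotropic point source one
#' transport mean free path (1/mu_s') below the surface position.
#'
#' @param xy surface position (x, y) in mm.
#' @param musp_background reduced scattering used for the depth rule, mm^-1.
#' @return length-3 point in mm.
#' @export
source_point <- function(xy, musp_background) {
  c(xy[1], xy[2], 1 / musp_background)
}
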