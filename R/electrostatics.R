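# Implicit-membrane continuum electrostatics for a solvated proton:
# Born radius from the hydration free energy, dielectric/screening map
# construction, cavity-point generation, and a finite-difference
# linearized Poisson-Boltzmann (FD-LPB) solver with multi-level
# focusing.  Internal energy unit: kJ/mol; the kcal->kJ factor 4.184
# enters once at the Born-equation boundary.

# e^2 / (4 pi eps0) in kJ Angstrom / mol: Coulomb energy of two unit
# charges 1 Angstrom apart in vacuum.
.coulomb_kJ <- 1389.35458
.kcal_to_kJ <- 4.184
.R_gas_kJ <- 8.31446261815324e-3  # kJ/mol/K

#' Effective Born radius from a hydration free energy
#'
#' Solves the Born equation a = -166 A kcal/mol q^2 / dG_solv x
#' (1 - 1/eps) for the cavity radius of an ion whose experimental
#' hydration free energy is known.  With q = +1 and the oxonium
#' hydration free energy -110.4 kcal/mol in water (eps = 80) this
#' gives the solvated-proton radius 1.4848 Angstrom.
#'
#' @param q ion charge, elementary charges (non-zero).
#' @param dG_solv hydration free energy, kcal/mol (negative).
#' @param eps_exterior solvent dielectric constant.
#' @return Born radius in Angstrom.
#' @export
born_radius <- function(q, dG_solv, eps_exterior = 80) {
  if (q == 0) stop("charge must be non-zero")
  if (dG_solv >= 0)
    stop("hydration free energy must be negative (bound ion)")
  -166 * q^2 / dG_solv * (1 - 1 / eps_exterior)
}

#' Born ion
#'
#' @param charge elementary charges.
#' @param radius cavity radius, Angstrom (> 0).
#' @export
born_ion <- function(charge = 1, radius) {
  stopifnot(radius > 0)
  structure(list(charge = charge, radius = radius), class = "born_ion")
}

#' Dielectric model of the solvated implicit-membrane system
#'
#' Bulk water eps 80, protein interior eps 10, a hydrophobic membrane
#' core of thickness 33.5 Angstrom with eps 2 flanked by head-group
#' slabs of thickness 6.5 Angstrom with eps 20 (hard shells); mobile
#' ions at the given ionic strength screen only in water voxels.
#'
#' @param eps_water,eps_protein,eps_core,eps_headgroup dielectric
#'   constants (>= 1).
#' @param core_thickness,headgroup_thickness slab thicknesses, Angstrom.
#' @param ionic_strength mol/L (1:1 salt).
#' @param temperature Kelvin.
#' @param probe_radius probe used to decide protein interior, Angstrom.
#' @return object of class `dielectric_model`.
#' @export
dielectric_model <- function(eps_water = 80, eps_protein = 10,
                             eps_core = 2, eps_headgroup = 20,
                             core_thickness = 33.5,
                             headgroup_thickness = 6.5,
                             ionic_strength = 0.1,
                             temperature = 298.15,
                             probe_radius = 1.4) {
  stopifnot(eps_water >= 1, eps_protein >= 1, eps_core >= 1,
            eps_headgroup >= 1, core_thickness > 0,
            headgroup_thickness > 0, ionic_strength >= 0,
            temperature > 0)
  structure(as.list(environment()), class = "dielectric_model")
}

#' Debye screening length
#'
#' For a 1:1 electrolyte: kappa^2 = 8 pi l_B n, with Bjerrum length
#' l_B = e^2/(4 pi eps0 eps kB T) and ion number density n.  About
#' 9.7 Angstrom in water (eps 80) at 100 mM and 298.15 K.
#'
#' @param ionic_strength mol/L.
#' @param eps relative dielectric of the medium.
#' @param temperature Kelvin.
#' @return Debye length in Angstrom (`Inf` at zero ionic strength).
#' @export
debye_length <- function(ionic_strength = 0.1, eps = 80,
                         temperature = 298.15) {
  if (ionic_strength <= 0) return(Inf)
  l_B <- .coulomb_kJ / (eps * .R_gas_kJ * temperature)
  n <- ionic_strength * 6.02214076e23 / 1e27  # per cubic Angstrom
  1 / sqrt(8 * pi * l_B * n)
}

# kappa_bar^2 (A^-2) used in the LPB operator: eps_water * kappa_D^2
kappa_bar2 <- function(model) {
  ld <- debye_length(model$ionic_strength, model$eps_water,
                     model$temperature)
  if (!is.finite(ld)) 0 else model$eps_water / ld^2
}

#' Multi-level focusing schedule
#'
#' Ordered cubic boxes of strictly decreasing edge, each solved on an
#' odd grid; every level takes its boundary values from the previous
#' level's solution (the first from a Debye-Hueckel monopole).  The
#' desk-scale default is (120, 65), (60, 65), (30, 65); the
#' larger-system schedule (250, 129), (100, 129), (50, 129) is
#' available via `scale = "paper"`.
#'
#' @param levels list of `c(box_edge_A, grid_points)` pairs; grid
#'   points must be odd.
#' @param scale shortcut: `"desk"` or `"paper"` default levels.
#' @return object of class `focusing_schedule`.
#' @export
focusing_schedule <- function(levels = NULL, scale = c("desk", "paper")) {
  if (is.null(levels)) {
    scale <- match.arg(scale)
    levels <- if (scale == "desk")
      list(c(120, 65), c(60, 65), c(30, 65))
    else list(c(250, 129), c(100, 129), c(50, 129))
  }
  edges <- vapply(levels, `[`, numeric(1), 1)
  npts <- vapply(levels, `[`, numeric(1), 2)
  stopifnot(all(diff(edges) < 0), all(npts %% 2 == 1), all(npts >= 9))
  structure(list(levels = levels), class = "focusing_schedule")
}

# node-centred cubic grid covering a box
lpb_grid <- function(center, edge, npts) {
  spacing <- edge / (npts - 1)
  list(origin = center - edge / 2, spacing = spacing,
       dims = rep(as.integer(npts), 3L))
}

grid_axis <- function(grid, ax)
  grid$origin[ax] + (seq_len(grid$dims[ax]) - 1L) * grid$spacing

#' Dielectric and screening maps for a structure in an implicit membrane
#'
#' Voxel dielectric values are assigned with precedence
#' solvent-accessible (eps water) > protein > head group > core >
#' water: a voxel is protein when its centre lies within vdW radius +
#' probe of an atom; membrane slabs are assigned by distance from the
#' midplane; `solvent_points` (e.g. from [cavity_points()]) reclaim
#' water-accessible interior voxels.  The screening map kappa_bar^2 is
#' non-zero only in water-dielectric voxels.
#'
#' @param structure a `structure3d` (or `NULL` for no protein).
#' @param model a [dielectric_model()].
#' @param grid list with `origin`, `spacing`, `dims` (see
#'   [build_grid()]).
#' @param solvent_points optional n x 3 matrix of water-accessible
#'   interior positions.
#' @param membrane logical: include the membrane slabs (midplane z=0).
#' @param ion_cavity optional list `(center, radius)`: a vacuum
#'   (eps = 1) spherical cavity representing the Born ion.
#' @return list with 3D arrays `eps` and `kappa2`.
#' @export
build_dielectric_map <- function(structure, model, grid,
                                 solvent_points = NULL, membrane = TRUE,
                                 ion_cavity = NULL) {
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2); zs <- grid_axis(grid, 3)
  d <- grid$dims
  eps <- array(model$eps_water, dim = d)
  if (membrane) {
    half_core <- model$core_thickness / 2
    half_total <- half_core + model$headgroup_thickness
    absz <- abs(zs)
    core_k <- which(absz < half_core)
    head_k <- which(absz >= half_core & absz < half_total)
    if (length(core_k)) eps[, , core_k] <- model$eps_core
    if (length(head_k)) eps[, , head_k] <- model$eps_headgroup
  }
  if (!is.null(structure)) {
    xyz <- coords(structure)
    reach <- structure$atoms$vdw + model$probe_radius
    if (nrow(xyz)) {
      for (a in seq_len(nrow(xyz))) {
        r <- reach[a]
        i <- which(abs(xs - xyz[a, 1]) <= r)
        j <- which(abs(ys - xyz[a, 2]) <= r)
        k <- which(abs(zs - xyz[a, 3]) <= r)
        if (!length(i) || !length(j) || !length(k)) next
        dx2 <- (xs[i] - xyz[a, 1])^2
        dy2 <- (ys[j] - xyz[a, 2])^2
        dz2 <- (zs[k] - xyz[a, 3])^2
        d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
        sub <- eps[i, j, k]
        sub[d2 <= r^2] <- model$eps_protein
        eps[i, j, k] <- sub
      }
    }
  }
  if (!is.null(solvent_points) && nrow(solvent_points)) {
    ii <- round((solvent_points[, 1] - grid$origin[1]) / grid$spacing) + 1
    jj <- round((solvent_points[, 2] - grid$origin[2]) / grid$spacing) + 1
    kk <- round((solvent_points[, 3] - grid$origin[3]) / grid$spacing) + 1
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    eps[cbind(ii[ok], jj[ok], kk[ok])] <- model$eps_water
  }
  if (!is.null(ion_cavity)) {
    # vacuum sphere with harmonic volume-fraction smoothing across the
    # surface: without it the effective cavity radius is quantized to
    # the grid and Born energies do not converge under refinement
    ctr <- ion_cavity$center; r <- ion_cavity$radius
    h <- grid$spacing
    i <- which(abs(xs - ctr[1]) <= r + 2 * h)
    j <- which(abs(ys - ctr[2]) <= r + 2 * h)
    k <- which(abs(zs - ctr[3]) <= r + 2 * h)
    if (length(i) && length(j) && length(k)) {
      d <- sqrt(outer(outer((xs[i] - ctr[1])^2, (ys[j] - ctr[2])^2, "+"),
                      (zs[k] - ctr[3])^2, "+"))
      f <- pmin(pmax(0.5 - (d - r) / h, 0), 1)  # inside fraction
      sub <- eps[i, j, k]
      sub <- 1 / (f / 1 + (1 - f) / sub)
      eps[i, j, k] <- sub
    }
  }
  kappa2 <- array(0, dim = d)
  kb2 <- kappa_bar2(model)
  if (kb2 > 0) kappa2[eps == model$eps_water] <- kb2
  list(eps = eps, kappa2 = kappa2)
}

#' Grid constructor
#'
#' @param origin first node position, Angstrom.
#' @param spacing node spacing, Angstrom.
#' @param dims integer 3-vector of node counts.
#' @return list with `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(origin, spacing, dims) {
  stopifnot(spacing > 0, length(dims) == 3L, all(dims >= 3))
  list(origin = as.numeric(origin), spacing = spacing,
       dims = as.integer(dims))
}

#' Lattice points where a probe sphere fits inside a bounding box
#'
#' Regular lattice points within `bounds` at which a probe of the
#' given radius does not overlap any atom's van der Waals sphere;
#' used to enumerate water-accessible cavity positions for the Born
#' landscape.  The lattice is clipped to the structure's bounding
#' region (bounding box padded by the probe radius).
#'
#' @param structure a `structure3d` (or `NULL`: the full lattice).
#' @param bounds list with 3-vectors `min`, `max`, Angstrom.
#' @param spacing lattice spacing, Angstrom.
#' @param probe probe radius, Angstrom.
#' @return n x 3 matrix of points (possibly empty).
#' @export
cavity_points <- function(structure, bounds, spacing = 1, probe = 1.4) {
  lo <- bounds$min; hi <- bounds$max
  stopifnot(all(hi > lo))
  if (!is.null(structure)) {
    xyz <- coords(structure)
    lo <- pmax(lo, apply(xyz, 2, min) - probe)
    hi <- pmin(hi, apply(xyz, 2, max) + probe)
    if (any(hi <= lo)) return(matrix(numeric(0), 0, 3))
  }
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = spacing))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(pts) <- NULL
  if (is.null(structure)) return(pts)
  xyz <- coords(structure)
  reach <- structure$atoms$vdw + probe
  keep <- rep(TRUE, nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    hit <- which(keep)
    if (!length(hit)) break
    d2 <- (pts[hit, 1] - xyz[a, 1])^2 + (pts[hit, 2] - xyz[a, 2])^2 +
      (pts[hit, 3] - xyz[a, 3])^2
    keep[hit[d2 < reach[a]^2]] <- FALSE
  }
  pts[keep, , drop = FALSE]
}

# Debye-Hueckel monopole boundary potential (kJ/mol per unit charge)
dh_potential <- function(pts, charges, eps, kappa_inv_A, min_r = 1e-6) {
  phi <- numeric(nrow(pts))
  for (c in seq_len(nrow(charges))) {
    r <- sqrt((pts[, 1] - charges$x[c])^2 + (pts[, 2] - charges$y[c])^2 +
                (pts[, 3] - charges$z[c])^2)
    r <- pmax(r, min_r)
    damp <- if (is.finite(kappa_inv_A)) exp(-r / kappa_inv_A) else 1
    phi <- phi + .coulomb_kJ * charges$q[c] * damp / (eps * r)
  }
  phi
}

# trilinear spread of point charges onto grid nodes
spread_charges <- function(charges, grid) {
  d <- grid$dims
  rho <- array(0, dim = d)
  for (c in seq_len(nrow(charges))) {
    f <- (c(charges$x[c], charges$y[c], charges$z[c]) - grid$origin) /
      grid$spacing
    i0 <- floor(f); w <- f - i0; i0 <- as.integer(i0) + 1L
    if (any(i0 < 1L) || any(i0 + 1L > d))
      stop("charge ", c, " lies outside (or on the boundary of) the grid")
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      if (wt > 0)
        rho[i0[1] + dx, i0[2] + dy, i0[3] + dz] <-
          rho[i0[1] + dx, i0[2] + dy, i0[3] + dz] + wt * charges$q[c]
    }
  }
  rho
}

# trilinear interpolation of a 3D nodal array at points (vectorized)
interp_trilinear <- function(values, grid, pts) {
  pts <- matrix(pts, ncol = 3)
  d <- grid$dims
  f <- sweep(pts, 2, grid$origin) / grid$spacing
  i0 <- pmin(pmax(floor(f), 0), matrix(rep(d - 2, each = nrow(f)),
                                       ncol = 3))
  w <- f - i0
  i0 <- i0 + 1L
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
      (if (dy == 1) w[, 2] else 1 - w[, 2]) *
      (if (dz == 1) w[, 3] else 1 - w[, 3])
    lin <- (i0[, 1] + dx) + (i0[, 2] + dy - 1) * d[1] +
      (i0[, 3] + dz - 1) * d[1] * d[2]
    out <- out + wt * values[lin]
  }
  out
}

# Preconditioned conjugate gradients for the SPD FD-LPB system.
cg_solve <- function(A, b, x0 = NULL, tol = 1e-6, maxit = 20000L) {
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - as.numeric(A %*% x)
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(numeric(length(b)))
  for (it in seq_len(maxit)) {
    if (sqrt(sum(r^2)) / bnorm < tol) return(x)
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("FD-LPB solver did not converge in %d iterations ",
               maxit),
       sprintf("(relative residual %.3g)", sqrt(sum(r^2)) / bnorm))
}

# Single-level FD-LPB solve with Dirichlet boundary values.
# eps, kappa2: nodal arrays; rho: nodal charge array (elementary
# charges); bvals: full-size array whose boundary entries are used.
solve_lpb_level <- function(eps, kappa2, rho, grid, bvals,
                            init = NULL, tol = 1e-6, maxit = 20000L) {
  d <- grid$dims; h <- grid$spacing
  n <- prod(d)
  idx <- array(seq_len(n), dim = d)
  bmask <- array(FALSE, dim = d)
  bmask[1, , ] <- TRUE; bmask[d[1], , ] <- TRUE
  bmask[, 1, ] <- TRUE; bmask[, d[2], ] <- TRUE
  bmask[, , 1] <- TRUE; bmask[, , d[3]] <- TRUE
  interior <- !bmask
  unk <- integer(n)
  unk[interior] <- seq_len(sum(interior))
  nu <- sum(interior)

  ti <- vector("list", 12); tj <- vector("list", 12); tv <- vector("list", 12)
  tk <- 0L
  b <- numeric(nu)

  for (ax in 1:3) {
    sl <- function(arr, rng) {
      if (ax == 1) arr[rng, , , drop = FALSE]
      else if (ax == 2) arr[, rng, , drop = FALSE]
      else arr[, , rng, drop = FALSE]
    }
    nAx <- d[ax]
    left <- as.vector(sl(idx, 1:(nAx - 1)))
    right <- as.vector(sl(idx, 2:nAx))
    ef <- 2 / (1 / eps[left] + 1 / eps[right]) * h  # face coefficient
    li <- interior[left]; ri <- interior[right]
    both <- li & ri
    # diagonal contributions (duplicates are summed by sparseMatrix)
    tk <- tk + 1L
    ti[[tk]] <- unk[left[li]]; tj[[tk]] <- unk[left[li]]; tv[[tk]] <- ef[li]
    tk <- tk + 1L
    ti[[tk]] <- unk[right[ri]]; tj[[tk]] <- unk[right[ri]]; tv[[tk]] <- ef[ri]
    # off-diagonals between interior pairs
    tk <- tk + 1L
    ti[[tk]] <- unk[left[both]]; tj[[tk]] <- unk[right[both]]
    tv[[tk]] <- -ef[both]
    tk <- tk + 1L
    ti[[tk]] <- unk[right[both]]; tj[[tk]] <- unk[left[both]]
    tv[[tk]] <- -ef[both]
    # boundary neighbours contribute to the RHS
    lb <- ri & !li
    if (any(lb)) {
      bi <- unk[right[lb]]
      b[bi] <- b[bi] + ef[lb] * bvals[left[lb]]
    }
    rb <- li & !ri
    if (any(rb)) {
      bi <- unk[left[rb]]
      b[bi] <- b[bi] + ef[rb] * bvals[right[rb]]
    }
  }

  kap_i <- which(kappa2[interior] != 0)
  A <- Matrix::sparseMatrix(
    i = c(unlist(ti), kap_i), j = c(unlist(tj), kap_i),
    x = c(unlist(tv), kappa2[interior][kap_i] * h^3), dims = c(nu, nu))
  b <- b + 4 * pi * .coulomb_kJ * rho[interior]  # charge term
  x0 <- if (is.null(init)) NULL else init[interior]
  phi_int <- cg_solve(A, b, x0 = x0, tol = tol, maxit = maxit)
  phi <- bvals
  phi[interior] <- phi_int
  phi
}

#' Solve the linearized Poisson-Boltzmann equation on one grid
#'
#' 7-point finite-difference discretisation with harmonic averaging of
#' the dielectric on face midpoints, trilinear charge assignment, a
#' Debye-Hueckel monopole outer boundary, and a Jacobi-preconditioned
#' conjugate-gradient solve to a relative residual of 1e-6.
#'
#' @param eps,kappa2 nodal 3D arrays (dielectric; screening, A^-2).
#' @param charges data frame with columns `x`, `y`, `z` (Angstrom) and
#'   `q` (elementary charges).
#' @param grid list with `origin`, `spacing`, `dims`.
#' @param eps_boundary,debye_boundary dielectric and Debye length
#'   (Angstrom) of the boundary monopole approximation.
#' @param bvals optional full-size array of Dirichlet boundary values
#'   (overrides the monopole boundary; used by focusing).
#' @param init optional initial-guess array.
#' @param tol,maxit convergence control.
#' @return 3D array of potentials, kJ/mol per elementary charge.
#' @export
solve_lpb <- function(eps, kappa2, charges, grid, eps_boundary = 80,
                      debye_boundary = Inf, bvals = NULL, init = NULL,
                      tol = 1e-6, maxit = 20000L) {
  if (all(charges$q == 0)) return(array(0, dim = grid$dims))
  rho <- spread_charges(charges, grid)
  if (is.null(bvals)) {
    # the monopole field over the whole grid also serves as the CG
    # initial guess (it is the exact solution for a homogeneous medium)
    d <- grid$dims
    pts <- as.matrix(expand.grid(grid_axis(grid, 1), grid_axis(grid, 2),
                                 grid_axis(grid, 3)))
    full <- array(dh_potential(pts, charges, eps_boundary,
                               debye_boundary, min_r = grid$spacing / 2),
                  dim = d)
    bvals <- full
    if (is.null(init)) init <- full
  }
  solve_lpb_level(eps, kappa2, rho, grid, bvals, init = init,
                  tol = tol, maxit = maxit)
}

#' Focused FD-LPB solve
#'
#' Solves on each level of a [focusing_schedule()] in turn; every
#' level after the first takes Dirichlet boundary values (and an
#' initial guess) interpolated from the previous level's solution.
#'
#' @param env_fn function(grid) returning `list(eps, kappa2)` nodal
#'   arrays for that grid (see [build_dielectric_map()]).
#' @param charges charge data frame (`x`, `y`, `z`, `q`).
#' @param schedule a [focusing_schedule()].
#' @param center 3-vector: common centre of the focusing boxes.
#' @param eps_boundary,debye_boundary boundary monopole parameters for
#'   the first (coarsest) level.
#' @param tol,maxit convergence control.
#' @return list with `potential` (3D array, kJ/mol/e) and `grid` of
#'   the finest level.
#' @export
solve_lpb_focused <- function(env_fn, charges, schedule, center,
                              eps_boundary = 80, debye_boundary = Inf,
                              tol = 1e-6, maxit = 20000L) {
  stopifnot(inherits(schedule, "focusing_schedule"))
  prev_phi <- NULL; prev_grid <- NULL
  for (lev in schedule$levels) {
    grid <- lpb_grid(center, lev[1], lev[2])
    env <- env_fn(grid)
    bvals <- NULL; init <- NULL
    if (!is.null(prev_phi)) {
      d <- grid$dims
      allpts <- as.matrix(expand.grid(grid_axis(grid, 1),
                                      grid_axis(grid, 2),
                                      grid_axis(grid, 3)))
      # expand.grid runs the first factor fastest, matching array order
      vals <- interp_trilinear(prev_phi, prev_grid, allpts)
      full <- array(vals, dim = d)
      bvals <- full
      init <- full
    }
    phi <- solve_lpb(env$eps, env$kappa2, charges, grid,
                     eps_boundary = eps_boundary,
                     debye_boundary = debye_boundary,
                     bvals = bvals, init = init, tol = tol, maxit = maxit)
    prev_phi <- phi; prev_grid <- grid
  }
  list(potential = prev_phi, grid = prev_grid)
}

# Reaction-field energy of a charge set: 1/2 sum q (phi_env - phi_ref)
# evaluated at the charge positions.  Identical grids and charge
# spreading make the grid self-energy cancel exactly.
reaction_field_energy <- function(charges, phi_env, phi_ref, grid) {
  pts <- as.matrix(charges[, c("x", "y", "z")])
  dphi <- interp_trilinear(phi_env, grid, pts) -
    interp_trilinear(phi_ref, grid, pts)
  0.5 * sum(charges$q * dphi)
}

# Focused two-solve (environment minus uniform-vacuum reference)
# reaction-field energy of an ion-cavity system centred on the ion.
ion_reaction_energy <- function(env_fn, ion, position, schedule,
                                eps_boundary, debye_boundary,
                                ref_cache = NULL, tol = 1e-6) {
  charges <- data.frame(x = position[1], y = position[2], z = position[3],
                        q = ion$charge)
  sol_env <- solve_lpb_focused(env_fn, charges, schedule, position,
                               eps_boundary = eps_boundary,
                               debye_boundary = debye_boundary, tol = tol)
  if (is.null(ref_cache)) {
    ref_fn <- function(grid) list(eps = array(1, grid$dims),
                                  kappa2 = array(0, grid$dims))
    sol_ref <- solve_lpb_focused(ref_fn, charges, schedule, position,
                                 eps_boundary = 1, debye_boundary = Inf,
                                 tol = tol)
    ref_cache <- sol_ref
  }
  # env and ref grids coincide by construction (same schedule, centred
  # on the ion), so the cached reference — computed once, geometry is
  # ion-relative — interpolates on the env grid
  e <- reaction_field_energy(charges, sol_env$potential,
                             ref_cache$potential, sol_env$grid)
  list(energy = e, ref_cache = ref_cache)
}

#' FD-LPB solvation free energy of a Born ion in uniform solvent
#'
#' Two-solve reaction-field scheme: the ion cavity (eps 1) in uniform
#' solvent minus the same system in uniform vacuum, on identical
#' focused grids, so grid self-energies cancel.  Converges to the
#' analytic Born energy -1389.35/(2a) (1 - 1/eps) q^2 kJ/mol as the
#' grid is refined.
#'
#' @param ion a [born_ion()].
#' @param eps_solvent solvent dielectric.
#' @param schedule a [focusing_schedule()].
#' @param center cavity centre (default origin).
#' @return solvation free energy, kJ/mol.
#' @export
born_solvation_energy <- function(ion, eps_solvent = 80,
                                  schedule = focusing_schedule(),
                                  center = c(0, 0, 0)) {
  env_fn <- function(grid) {
    m <- dielectric_model(eps_water = eps_solvent, ionic_strength = 0)
    build_dielectric_map(NULL, m, grid, membrane = FALSE,
                         ion_cavity = list(center = center,
                                           radius = ion$radius))
  }
  ion_reaction_energy(env_fn, ion, center, schedule,
                      eps_boundary = eps_solvent,
                      debye_boundary = Inf)$energy
}

#' Analytic Born solvation energy
#'
#' @param ion a [born_ion()].
#' @param eps_solvent solvent dielectric.
#' @return kJ/mol.
#' @export
born_energy_analytic <- function(ion, eps_solvent = 80) {
  -.coulomb_kJ * ion$charge^2 / (2 * ion$radius) * (1 - 1 / eps_solvent)
}

#' Position-resolved electrostatic free energy of a solvated ion
#'
#' For each position r, the Born landscape W(r) is the free energy of
#' the ion bound to the (membrane-embedded) protein relative to ion
#' and protein separately in bulk:
#' W(r) = G(protein + ion at r) - G(protein) - G(ion in bulk).
#' All G terms are reaction-field (two-solve) energies on identical
#' ion-centred focused grids, so grid self-energies cancel; by
#' linearity of the LPB the protein self-terms drop out and W(r)
#' reduces to the ion desolvation difference plus the protein-ion
#' interaction term.
#'
#' @param structure a `structure3d` with charges (e.g. from
#'   [read_pqr()]), or `NULL` for a protein-free membrane system.
#' @param ion a [born_ion()].
#' @param model a [dielectric_model()].
#' @param schedule a [focusing_schedule()].
#' @param points n x 3 matrix of ion positions (e.g. from
#'   [cavity_points()]).
#' @param solvent_points optional water-accessible interior positions
#'   passed to [build_dielectric_map()].
#' @param membrane include the implicit membrane slabs.
#' @param verbose print per-point progress.
#' @return data frame `x`, `y`, `z`, `W` (kJ/mol), `flagged` (TRUE for
#'   points whose unperturbed environment is below the water
#'   dielectric: desolvation regime).
#' @export
born_landscape <- function(structure, ion, model = dielectric_model(),
                           schedule = focusing_schedule(), points,
                           solvent_points = NULL, membrane = TRUE,
                           verbose = FALSE) {
  points <- matrix(points, ncol = 3)
  dl <- debye_length(model$ionic_strength, model$eps_water,
                     model$temperature)

  env_fn_at <- function(pos) {
    function(grid) build_dielectric_map(structure, model, grid,
                                        solvent_points = solvent_points,
                                        membrane = membrane,
                                        ion_cavity = list(center = pos,
                                                          radius = ion$radius))
  }

  # G(ion in bulk): computed once (geometry is ion-relative)
  bulk_center <- c(0, 0, 0)
  bulk_env <- function(grid) {
    build_dielectric_map(NULL, model, grid, membrane = FALSE,
                         ion_cavity = list(center = bulk_center,
                                           radius = ion$radius))
  }
  res0 <- ion_reaction_energy(bulk_env, ion, bulk_center, schedule,
                              eps_boundary = model$eps_water,
                              debye_boundary = dl)
  G_ion_bulk <- res0$energy
  ref_cache <- res0$ref_cache

  # protein potential in the environment, for the ion-protein
  # interaction term q_I phi_P(r); solved once on a protein-centred
  # schedule.  The protein self-energy cancels between G(protein+ion)
  # and G(protein) and never enters.
  phi_P_env <- NULL
  if (!is.null(structure) && any(structure$atoms$charge != 0)) {
    pcenter <- colMeans(coords(structure))
    pcharges <- data.frame(x = structure$atoms$x, y = structure$atoms$y,
                           z = structure$atoms$z,
                           q = structure$atoms$charge)
    pcharges <- pcharges[pcharges$q != 0, ]
    penv_fn <- function(grid) build_dielectric_map(structure, model, grid,
                                                   solvent_points = solvent_points,
                                                   membrane = membrane)
    sol_env <- solve_lpb_focused(penv_fn, pcharges, schedule, pcenter,
                                 eps_boundary = model$eps_water,
                                 debye_boundary = dl)
    phi_P_env <- list(pot = sol_env$potential, grid = sol_env$grid)
  }

  W <- numeric(nrow(points)); flagged <- logical(nrow(points))
  for (p in seq_len(nrow(points))) {
    pos <- points[p, ]
    res <- ion_reaction_energy(env_fn_at(pos), ion, pos, schedule,
                               eps_boundary = model$eps_water,
                               debye_boundary = dl,
                               ref_cache = ref_cache)
    W[p] <- res$energy - G_ion_bulk
    if (!is.null(phi_P_env)) {
      W[p] <- W[p] + ion$charge *
        interp_trilinear(phi_P_env$pot, phi_P_env$grid,
                         matrix(pos, 1, 3))
    }
    # flag desolvation-regime points: environment without the cavity
    probe_grid <- build_grid(pos - 1, 1, c(3, 3, 3))
    env0 <- build_dielectric_map(structure, model, probe_grid,
                                 solvent_points = solvent_points,
                                 membrane = membrane)
    flagged[p] <- env0$eps[2, 2, 2] < model$eps_water
    if (verbose)
      message(sprintf("point %d/%d: W = %.2f kJ/mol%s", p, nrow(points),
                      W[p], if (flagged[p]) " (desolvation regime)" else ""))
  }
  data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
             W = W, flagged = flagged)
}

#' Electrostatic barrier profile of a protein-free implicit membrane
#'
#' Convenience wrapper around [born_landscape()] with no protein:
#' W(z) along the membrane normal for an ion moved from bulk water
#' into the low-dielectric core.
#'
#' @param ion a [born_ion()].
#' @param model a [dielectric_model()].
#' @param schedule a [focusing_schedule()].
#' @param z_points heights along the membrane normal, Angstrom.
#' @param verbose print progress.
#' @return data frame `z`, `W` (kJ/mol), `flagged`.
#' @export
membrane_barrier_profile <- function(ion, model = dielectric_model(),
                                     schedule = focusing_schedule(),
                                     z_points = c(35, 28, 23, 18, 12, 6, 0),
                                     verbose = FALSE) {
  pts <- cbind(0, 0, z_points)
  out <- born_landscape(NULL, ion, model, schedule, pts,
                        verbose = verbose)
  data.frame(z = z_points, W = out$W, flagged = out$flagged)
}
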