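# Permeation-pathway characterisation: a simplified pore-radius
# profiler (largest sphere fitting in a membrane-normal slab, per z),
# water-density gridding relative to bulk, and aqueous-pathway
# connectivity between compartments.

#' Regular 3D scalar field
#'
#' @param origin coordinates of the first voxel centre, Angstrom.
#' @param spacing isotropic voxel spacing, Angstrom.
#' @param values 3D numeric array.
#' @param semantics one of `"count"`, `"relative_density"`,
#'   `"dielectric"`, `"screening"`, `"potential"`, `"energy"`.
#' @return object of class `scalar_field3d`.
#' @export
scalar_field3d <- function(origin, spacing, values,
                           semantics = c("count", "relative_density",
                                         "dielectric", "screening",
                                         "potential", "energy")) {
  semantics <- match.arg(semantics)
  stopifnot(length(origin) == 3L, spacing > 0, length(dim(values)) == 3L,
            all(is.finite(values)))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 values = values, semantics = semantics),
            class = "scalar_field3d")
}

#' @export
print.scalar_field3d <- function(x, ...) {
  cat(sprintf("scalar_field3d [%s]: %s voxels, spacing %.3g A, origin (%s)\n",
              x$semantics, paste(dim(x$values), collapse = "x"),
              x$spacing, paste(sprintf("%.2f", x$origin), collapse = ", ")))
  invisible(x)
}

# voxel-centre coordinates along one axis
axis_centers <- function(field, ax) {
  field$origin[ax] + (seq_len(dim(field$values)[ax]) - 1L) * field$spacing
}

#' Pore radius in a membrane-normal slab
#'
#' The radius at height z is the largest clearance sphere that can be
#' centred in the plane: the maximum over in-plane centres c of the
#' minimum over slab atoms of (distance from (c, z) to the atom centre
#' minus its van der Waals radius), clamped at zero.  The maximisation
#' uses a 5 x 5 grid of starts refined by Nelder-Mead, so it is
#' deterministic; for kinked pathways whose centreline leaves the
#' plane the profile may differ from a path-following probe.
#'
#' @param frame a `structure3d`.
#' @param z slab height, Angstrom (membrane frame).
#' @param xy_start in-plane search centre; default the slab centroid.
#' @param box_half half-width of the in-plane search box, Angstrom.
#'   The default (5) is cavity-scale: it keeps the search inside a
#'   transporter bore; a wide box reports the boundary-limited maximum
#'   when the true clearance is unbounded outward.
#' @param slab_half half-thickness of the atom slab, Angstrom.
#' @param membrane a [membrane_frame()].
#' @return list with `radius` (Angstrom; `Inf` sentinel when the slab
#'   is empty, i.e. the radius is unbounded) and `center` (xy).
#' @export
pore_radius_at <- function(frame, z, xy_start = NULL, box_half = 5,
                           slab_half = 3, membrane = membrane_frame()) {
  xyz <- coords(frame)
  zc <- membrane_coord(xyz, membrane)
  sel <- abs(zc - z) <= slab_half
  if (!any(sel))
    return(list(radius = Inf, center = c(NA_real_, NA_real_)))
  ax <- setdiff(1:3, match(membrane$normal_axis, c("x", "y", "z")))
  pa <- xyz[sel, ax, drop = FALSE]
  dz <- zc[sel] - z
  vdw <- frame$atoms$vdw[sel]
  if (is.null(xy_start)) xy_start <- colMeans(pa)
  clearance <- function(c2) {
    min(sqrt((pa[, 1] - c2[1])^2 + (pa[, 2] - c2[2])^2 + dz^2) - vdw)
  }
  obj <- function(c2) {
    # keep the centre inside the search box (boundary-limited maximum)
    if (any(abs(c2 - xy_start) > box_half)) return(1e6)
    -clearance(c2)
  }
  starts <- expand.grid(x = seq(-1, 1, length.out = 5) * box_half * 0.8,
                        y = seq(-1, 1, length.out = 5) * box_half * 0.8)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    st <- xy_start + as.numeric(starts[s, ])
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 400))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(radius = max(-best$value, 0), center = as.numeric(best$par))
}

#' Ensemble pore-radius profile along the membrane normal
#'
#' Per-frame radii at each z are aggregated into a mean and standard
#' deviation per bin, mirroring ensemble-averaged pore profiles with a
#' 1 SD band.
#'
#' @param ensemble an `ensemble3d` (a `structure3d` is treated as one
#'   frame).
#' @param z_grid monotone vector of slab heights, Angstrom.
#' @param membrane a [membrane_frame()].
#' @param stride analyse every `stride`-th frame.
#' @param ... passed to [pore_radius_at()].
#' @return data frame `z`, `mean_radius`, `sd_radius`, `n` (frames with
#'   a bounded radius at that z).
#' @export
pore_profile <- function(ensemble, z_grid, membrane = membrane_frame(),
                         stride = 1L, ...) {
  if (inherits(ensemble, "structure3d"))
    ensemble <- ensemble3d(ensemble, list(coords(ensemble)))
  stopifnot(inherits(ensemble, "ensemble3d"),
            all(diff(z_grid) > 0) || all(diff(z_grid) < 0))
  idx <- seq(1L, n_frames(ensemble), by = stride)
  radii <- matrix(NA_real_, length(idx), length(z_grid))
  for (k in seq_along(idx)) {
    fr <- get_frame(ensemble, idx[k])
    radii[k, ] <- vapply(z_grid, function(z) {
      pore_radius_at(fr, z, membrane = membrane, ...)$radius
    }, numeric(1))
  }
  finite <- is.finite(radii)
  data.frame(
    z = z_grid,
    mean_radius = vapply(seq_along(z_grid), function(j) {
      v <- radii[finite[, j], j]; if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    sd_radius = vapply(seq_along(z_grid), function(j) {
      v <- radii[finite[, j], j]
      # population SD: descriptive spread of the frame ensemble
      if (length(v) >= 1L) sqrt(mean((v - mean(v))^2)) else NA_real_
    }, numeric(1)),
    n = colSums(finite))
}

#' Number density of SPC bulk water
#'
#' 0.970 g/cm^3 converted to waters per cubic Angstrom
#' (0.970 / 18.0154 g/mol x Avogadro), about 0.0324 A^-3.
#'
#' @return number density in A^-3.
#' @export
spc_bulk_number_density <- function() {
  0.970 / 18.0154 * 6.02214076e23 / 1e24
}

#' Time-averaged water density on a grid, relative to bulk
#'
#' Waters are binned into voxels per frame; the per-voxel mean number
#' density over frames is divided by the bulk number density.  Waters
#' outside the grid are dropped and counted.
#'
#' @param waters a `water_frames` list (or a single n x 3 matrix).
#' @param origin,spacing,dims grid definition: first voxel centre
#'   (Angstrom), voxel spacing (Angstrom), integer extents.
#' @param bulk_number_density bulk reference, A^-3 (default SPC water).
#' @return `scalar_field3d` with semantics `"relative_density"`;
#'   attributes `counts` (raw 3D count array summed over frames),
#'   `n_frames` and `dropped`.
#' @export
water_density <- function(waters, origin, spacing = 1, dims,
                          bulk_number_density = spc_bulk_number_density()) {
  stopifnot(bulk_number_density > 0, length(dims) == 3L)
  if (is.matrix(waters)) waters <- list(waters)
  counts <- array(0, dim = dims)
  dropped <- 0L
  for (w in waters) {
    if (!nrow(w)) next
    # voxel index of the containing voxel (centres at origin + (i-1)*h)
    ijk <- sweep(w, 2, origin - spacing / 2)
    ijk <- floor(sweep(ijk, 2, rep(spacing, 3), "/")) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
    dropped <- dropped + sum(!ok)
    ijk <- ijk[ok, , drop = FALSE]
    for (r in seq_len(nrow(ijk)))
      counts[ijk[r, 1], ijk[r, 2], ijk[r, 3]] <-
        counts[ijk[r, 1], ijk[r, 2], ijk[r, 3]] + 1
  }
  if (dropped > 0L)
    message(dropped, " water position(s) outside the grid were dropped")
  dens <- counts / (length(waters) * spacing^3) / bulk_number_density
  out <- scalar_field3d(origin, spacing, dens, "relative_density")
  attr(out, "counts") <- counts
  attr(out, "n_frames") <- length(waters)
  attr(out, "dropped") <- dropped
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
  }
}

# connected-component labelling of a logical 3D mask (BFS)
label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  offs <- neighbor_offsets(connectivity)
  nvox <- prod(dims)
  queue <- integer(nvox)
  current <- 0L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    lab[start] <- current
    queue[1L] <- start; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      v0 <- v - 1L
      i <- v0 %% dims[1] + 1L
      j <- (v0 %/% dims[1]) %% dims[2] + 1L
      k <- v0 %/% (dims[1] * dims[2]) + 1L
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
        if (ii < 1L || ii > dims[1] || jj < 1L || jj > dims[2] ||
            kk < 1L || kk > dims[3]) next
        w <- ii + (jj - 1L) * strides[2] + (kk - 1L) * strides[3]
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- current
          qt <- qt + 1L; queue[qt] <- w
        }
      }
    }
  }
  lab
}

region_voxels <- function(field, region) {
  idx <- lapply(1:3, function(ax) {
    ctr <- axis_centers(field, ax)
    which(ctr >= region$min[ax] & ctr <= region$max[ax])
  })
  if (any(!vapply(idx, length, integer(1))))
    stop("region does not intersect the grid")
  idx
}

#' Aqueous-pathway connectivity between two compartments
#'
#' Thresholds the density field and asks whether one connected
#' component of at-or-above-threshold voxels intersects both regions.
#' Default 26-connectivity; 6-connectivity gives stricter calls.
#'
#' @param field a `scalar_field3d` (relative density).
#' @param threshold density threshold.
#' @param regionA,regionB axis-aligned boxes, each a list with 3-vector
#'   `min` and `max` in Angstrom.
#' @param connectivity 6 or 26.
#' @return list with `connected` (logical) and `components` (integer
#'   3D label array, 0 below threshold).
#' @export
pathway_connected <- function(field, threshold, regionA, regionB,
                              connectivity = 26) {
  stopifnot(inherits(field, "scalar_field3d"),
            connectivity %in% c(6, 26))
  mask <- field$values >= threshold
  lab <- label_components(mask, connectivity)
  ra <- region_voxels(field, regionA)
  rb <- region_voxels(field, regionB)
  la <- unique(as.vector(lab[ra[[1]], ra[[2]], ra[[3]]]))
  lb <- unique(as.vector(lab[rb[[1]], rb[[2]], rb[[3]]]))
  shared <- intersect(setdiff(la, 0L), setdiff(lb, 0L))
  list(connected = length(shared) > 0L, components = lab)
}

# ---------------------------------------------------------------------------
# OpenDX volumetric format
# ---------------------------------------------------------------------------

#' Write a scalar field in OpenDX format
#'
#' Standard `gridpositions`/`gridconnections`/`array` layout with the
#' last (z) index varying fastest, interoperable with common volume
#' viewers.
#'
#' @param field a `scalar_field3d`.
#' @param path output file.
#' @export
write_dx <- function(field, path) {
  d <- dim(field$values)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX scalar field (%s) written by gatescape",
            field$semantics),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", field$origin[1], field$origin[2],
            field$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", field$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", field$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", field$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d",
                   " data follows"), prod(d))), con)
  # z fastest: iterate x, y, z in row-major triples
  v <- aperm(field$values, c(3, 2, 1))  # now v[z,y,x]; as.vector runs z first
  v <- as.vector(v)
  n <- length(v)
  full <- seq_len(n - n %% 3)
  if (length(full)) {
    m <- matrix(v[full], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n %% 3)
    writeLines(paste(sprintf("%.6e", v[(n - n %% 3 + 1):n]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#'
#' @param path OpenDX file.
#' @param semantics semantics tag for the returned field.
#' @return a `scalar_field3d`.
#' @export
read_dx <- function(path, semantics = "count") {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  d <- as.integer(tail(strsplit(gp, "[[:space:]]+")[[1]], 3))
  org <- as.numeric(strsplit(trimws(sub("^origin", "",
                                        grep("^origin", lines,
                                             value = TRUE)[1])),
                             "[[:space:]]+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  sp <- as.numeric(strsplit(trimws(sub("^delta", "", deltas[1])),
                            "[[:space:]]+")[[1]])[1]
  data_start <- grep("data follows", lines)[1] + 1L
  data_end <- grep("^attribute", lines)[1] - 1L
  v <- as.numeric(unlist(strsplit(trimws(lines[data_start:data_end]),
                                  "[[:space:]]+")))
  stopifnot(length(v) == prod(d))
  arr <- aperm(array(v, dim = rev(d)), c(3, 2, 1))
  scalar_field3d(org, sp, arr, semantics)
}
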