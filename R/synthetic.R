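# Synthetic membrane-protein-like fixtures: a two-domain helical bundle
# with independently tunable cytoplasmic (z < 0) and periplasmic (z > 0)
# gate openings, transition ensembles, a toy Brownian soft-ratchet
# sampler, weighted rotamer libraries and cavity waters.

#' Specification of a synthetic two-domain helical bundle
#'
#' The bundle emulates the two-domain MFS architecture: two half-rings
#' of idealized helices around the z axis (domains A and B), whose
#' helix ends splay away from the opposite domain on the cytoplasmic
#' (z < 0) and periplasmic (z > 0) halves by independently tunable
#' fractions of `max_splay`.
#'
#' @param n_helices_per_domain helices per domain (>= 2).
#' @param helix_length residues per helix.
#' @param rise_per_residue helical rise, Angstrom.
#' @param bundle_radius radius of the helix ring, Angstrom.
#' @param gate_cyt,gate_peri gate opening fractions in `[0, 1]`.
#' @param max_splay terminal splay displacement at full opening, Angstrom.
#' @param max_pinch inward radial displacement of the helix ends at
#'   full closure, Angstrom; it constricts the central bore below the
#'   radius of a water molecule at a closed face.
#' @param seed integer seed for the (small, fixed-amplitude) coordinate
#'   jitter that keeps fixtures from being exactly degenerate.
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices_per_domain = 6, helix_length = 20,
                        rise_per_residue = 1.5, bundle_radius = 9,
                        gate_cyt = 0, gate_peri = 0, max_splay = 8,
                        max_pinch = 5, seed = 1) {
  stopifnot(n_helices_per_domain >= 2,
            gate_cyt >= 0, gate_cyt <= 1,
            gate_peri >= 0, gate_peri <= 1,
            helix_length >= 2, rise_per_residue > 0, bundle_radius > 0)
  structure(as.list(environment()), class = "bundle_spec")
}

# Idealized backbone for one helix: N, CA, C per residue on a spiral
# around a vertical axis through `center_xy`.  `phase0` orients the
# spiral so that residue 1 points toward the bundle axis.
helix_backbone <- function(center_xy, theta, helix_length, rise) {
  i <- seq_len(helix_length)
  z <- (i - (helix_length + 1) / 2) * rise
  xhat <- c(cos(theta), sin(theta))   # radial (outward) unit vector
  yhat <- c(-sin(theta), cos(theta))  # tangential
  spiral <- function(phase_deg, r, dz) {
    ph <- (100 * (i - 1) + phase_deg) * pi / 180
    cbind(center_xy[1] + r * (cos(ph) * xhat[1] + sin(ph) * yhat[1]),
          center_xy[2] + r * (cos(ph) * xhat[2] + sin(ph) * yhat[2]),
          z + dz)
  }
  list(N  = spiral(145, 1.9, -0.55),
       CA = spiral(180, 2.3, 0),
       C  = spiral(215, 1.9, 0.55))
}

#' Generate a synthetic two-domain helical bundle
#'
#' Deterministic for a fixed spec (including its seed).  Each membrane
#' half responds only to its own gate fraction: at full closure the
#' helix ends pinch radially inward (sealing the bore at that face);
#' at full opening they splay away from the opposite domain, so the
#' inter-domain gate distance grows monotonically with the fraction.
#' The designated
#' gate anchor residues — the terminal Calpha of the seam helix of each
#' domain at each face — are recorded in `$anchors` and summarised in
#' the structure label; [bundle_gate_pairs()] turns them into gate
#' definitions.
#'
#' @param spec a [bundle_spec()].
#' @return a `structure3d` with chains "A" and "B".
#' @export
make_bundle <- function(spec = bundle_spec()) {
  stopifnot(inherits(spec, "bundle_spec"))
  n <- spec$n_helices_per_domain
  L <- spec$helix_length
  half_span <- (L - 1) / 2 * spec$rise_per_residue
  # domain half-rings; the inter-domain seam sits at +90 degrees
  ang_A <- (90 + (seq_len(n) - 0.5) * 180 / n) * pi / 180
  ang_B <- (-90 + (seq_len(n) - 0.5) * 180 / n) * pi / 180
  dom_dir <- list(A = c(-1, 0), B = c(1, 0))  # away from the other domain

  rows <- list()
  resid0 <- list(A = 0L, B = 1000L)
  seam_helix <- list(A = 1L, B = n)  # helix nearest the seam per domain
  anchors <- list()
  helix_theta <- numeric(0)  # per-atom helix azimuth, for the pinch
  for (dom in c("A", "B")) {
    angs <- if (dom == "A") ang_A else ang_B
    for (h in seq_len(n)) {
      ctr <- spec$bundle_radius * c(cos(angs[h]), sin(angs[h]))
      bb <- helix_backbone(ctr, angs[h], L, spec$rise_per_residue)
      resids <- resid0[[dom]] + (h - 1L) * L + seq_len(L)
      for (at in c("N", "CA", "C")) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = at, element = substr(at, 1, 1), resname = "ALA",
          resid = rep(resids, 1), chain = dom,
          x = bb[[at]][, 1], y = bb[[at]][, 2], z = bb[[at]][, 3],
          stringsAsFactors = FALSE)
        helix_theta <- c(helix_theta, rep(angs[h], L))
      }
      if (h == seam_helix[[dom]]) {
        anchors[[paste0("cyt_", dom)]] <- list(chain = dom,
                                               resid = resids[1L])
        anchors[[paste0("peri_", dom)]] <- list(chain = dom,
                                                resid = resids[L])
      }
    }
  }
  atoms <- do.call(rbind, rows)
  ord <- order(match(atoms$chain, c("A", "B")), atoms$resid,
               match(atoms$name, c("N", "CA", "C")))
  atoms <- atoms[ord, , drop = FALSE]
  helix_theta <- helix_theta[ord]

  # fixed-amplitude jitter, drawn once from the seed before the gate
  # displacements so that each gate's geometry depends only on its own
  # fraction
  set.seed(spec$seed)
  jit <- matrix(rnorm(3L * nrow(atoms), sd = 0.05), ncol = 3)
  atoms$x <- atoms$x + jit[, 1]
  atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]

  # gate displacements, linear in |z| / half_span, scaled by the gate
  # fraction of the atom's membrane half: opening splays the domains
  # apart, closing pinches the helix ends onto the bundle axis
  frac <- ifelse(atoms$z < 0, spec$gate_cyt, spec$gate_peri)
  taper <- pmin(abs(atoms$z) / half_span, 1)
  dirx <- ifelse(atoms$chain == "A", dom_dir$A[1], dom_dir$B[1])
  splay <- frac * spec$max_splay * taper
  pinch <- (1 - frac) * spec$max_pinch * taper
  atoms$x <- atoms$x + splay * dirx - pinch * cos(helix_theta)
  atoms$y <- atoms$y - pinch * sin(helix_theta)

  label <- sprintf("synthetic bundle gate_cyt=%.3f gate_peri=%.3f seed=%d",
                   spec$gate_cyt, spec$gate_peri, spec$seed)
  structure3d(atoms, label = label, anchors = anchors)
}

#' Interpolated transition ensemble between two conformations
#'
#' Linear coordinate interpolation from `start` to `end` plus isotropic
#' Gaussian noise; with zero noise the first and last frames equal the
#' end states exactly.
#'
#' @param start,end `structure3d` objects sharing one topology.
#' @param n_frames number of frames (>= 2).
#' @param noise_sigma per-coordinate noise SD, Angstrom.
#' @param seed integer seed.
#' @return an `ensemble3d`.
#' @export
make_transition <- function(start, end, n_frames, noise_sigma = 0,
                            seed = 1) {
  stopifnot(inherits(start, "structure3d"), inherits(end, "structure3d"),
            n_frames >= 2)
  if (!identical(start$atoms[, c("name", "resname", "resid", "chain")],
                 end$atoms[, c("name", "resname", "resid", "chain")]))
    stop("start and end structures do not share a topology")
  a <- coords(start); b <- coords(end)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(j) {
    t <- (j - 1) / (n_frames - 1)
    f <- (1 - t) * a + t * b
    if (noise_sigma > 0)
      f <- f + matrix(rnorm(length(f), sd = noise_sigma), ncol = 3)
    f
  })
  ensemble3d(start, frames)
}

#' Soft-ratchet sampler configuration
#'
#' @param delta_phi softness scale of the ratchet, Angstrom.  Small
#'   values (e.g. 1e-6) give a nearly hard ratchet that essentially
#'   never accepts backward steps; 1e-4 is a soft ratchet.
#' @param step_sigma Brownian proposal SD per coordinate per step,
#'   Angstrom.
#' @param max_steps proposal budget.
#' @param seed integer seed.
#' @export
soft_ratchet_config <- function(delta_phi = 1e-4, step_sigma = 0.05,
                                max_steps = 1000L, seed = 1) {
  stopifnot(delta_phi > 0, step_sigma > 0, max_steps >= 1)
  structure(list(delta_phi = delta_phi, step_sigma = step_sigma,
                 max_steps = as.integer(max_steps), seed = seed),
            class = "soft_ratchet_config")
}

#' Toy Brownian soft-ratchet sampler toward a target conformation
#'
#' Gaussian coordinate proposals are accepted unconditionally when they
#' do not increase the progress variable phi — the best-fit RMSD of
#' `progress_atoms` to the target — and with probability
#' `exp(-delta/delta_phi)` when they increase it by `delta`.  The run
#' ends after `max_steps` proposals or once phi < 0.5 Angstrom.  The
#' refit of the target is performed at every evaluation.
#'
#' @param start,target `structure3d` objects sharing one topology.
#' @param cfg a [soft_ratchet_config()].
#' @param progress_atoms indices of the atoms entering phi.
#' @return an `ensemble3d` of the accepted states (the start state is
#'   frame 1); attribute `phi` holds the per-frame progress values.
#' @export
soft_ratchet_sample <- function(start, target, cfg = soft_ratchet_config(),
                                progress_atoms) {
  stopifnot(inherits(start, "structure3d"), inherits(target, "structure3d"))
  if (nrow(start$atoms) != nrow(target$atoms))
    stop("start and target structures do not share a topology")
  if (length(progress_atoms) < 1L) stop("progress_atoms must be non-empty")
  tgt <- coords(target)[progress_atoms, , drop = FALSE]
  x <- coords(start)
  phi <- superpose_rmsd(x[progress_atoms, , drop = FALSE], tgt)
  frames <- list(x)
  phis <- phi
  set.seed(cfg$seed)
  for (s in seq_len(cfg$max_steps)) {
    if (phi < 0.5) break
    y <- x + matrix(rnorm(length(x), sd = cfg$step_sigma), ncol = 3)
    phi_new <- superpose_rmsd(y[progress_atoms, , drop = FALSE], tgt)
    delta <- phi_new - phi
    if (delta <= 0 || runif(1) < exp(-delta / cfg$delta_phi)) {
      x <- y; phi <- phi_new
      frames[[length(frames) + 1L]] <- x
      phis <- c(phis, phi)
    }
  }
  out <- ensemble3d(start, frames)
  attr(out, "phi") <- phis
  out
}

#' Synthetic weighted rotamer library
#'
#' Short articulated arms in the canonical side-chain frame (the frame
#' [attach_rotamers()] builds from the backbone N, CA, C anchors:
#' origin at CA, x toward N), with Dirichlet-distributed weights.  The
#' last two arm atoms ("N1", "O1") are the reporter atoms whose
#' midpoint is the spin position.
#'
#' @param n_rotamers number of rotamers (>= 1).
#' @param arm_length approximate arm extent, Angstrom.
#' @param seed integer seed.
#' @param n_atoms atoms per arm (>= 2).
#' @return object of class `rotamer_library`.
#' @export
make_rotamer_library <- function(n_rotamers, arm_length = 7, seed = 1,
                                 n_atoms = 5L) {
  stopifnot(n_rotamers >= 1, n_atoms >= 2, arm_length > 0)
  set.seed(seed)
  atom_names <- c("SG", "C1", "C2", "N1", "O1")[seq_len(min(n_atoms, 5L))]
  if (n_atoms > 5L) atom_names <- c(atom_names,
                                    paste0("X", seq_len(n_atoms - 5L)))
  seg <- arm_length / n_atoms
  coords <- lapply(seq_len(n_rotamers), function(k) {
    # random-direction walk with persistence, starting off the backbone
    dir <- c(-0.4, -0.7, 0.6); dir <- dir / sqrt(sum(dir^2))
    pos <- matrix(0, n_atoms, 3)
    p <- c(0, 0, 0)
    for (j in seq_len(n_atoms)) {
      kick <- rnorm(3, sd = 0.6)
      dir <- dir + kick; dir <- dir / sqrt(sum(dir^2))
      p <- p + seg * dir
      pos[j, ] <- p
    }
    pos
  })
  w <- rgamma(n_rotamers, shape = 1)
  rotamer_library(coords = coords, weights = w / sum(w),
                  atom_names = atom_names,
                  anchor_names = c("N", "CA", "C"),
                  reporter_names = tail(atom_names, 2L))
}

#' Construct a rotamer library
#'
#' @param coords list of m x 3 matrices, one per rotamer, in the
#'   canonical side-chain frame.
#' @param weights positive rotamer weights; normalized to sum 1.
#' @param atom_names atom names shared by all rotamers.
#' @param anchor_names three backbone atom names defining the
#'   attachment frame.
#' @param reporter_names two atom names whose midpoint is the spin
#'   position.
#' @return object of class `rotamer_library`.
#' @export
rotamer_library <- function(coords, weights, atom_names,
                            anchor_names = c("N", "CA", "C"),
                            reporter_names) {
  stopifnot(length(coords) == length(weights), length(coords) >= 1,
            all(weights > 0), length(anchor_names) == 3L,
            length(reporter_names) == 2L,
            all(reporter_names %in% atom_names))
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(atom_names) || ncol(m) != 3L)
      stop("every rotamer must have one 3-vector per atom name")
    dimnames(m) <- NULL
    m
  })
  structure(list(coords = coords, weights = weights / sum(weights),
                 atom_names = atom_names, anchor_names = anchor_names,
                 reporter_names = reporter_names),
            class = "rotamer_library")
}

#' Write a rotamer library as plain text
#'
#' Format: a header with atom, anchor and reporter names, then one
#' block per rotamer (`ROTAMER k weight` followed by one `x y z` line
#' per atom).
#'
#' @param lib a `rotamer_library`.
#' @param path output file.
#' @export
write_rotamer_library <- function(lib, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ATOMS", paste(lib$atom_names, collapse = " ")),
               paste("ANCHORS", paste(lib$anchor_names, collapse = " ")),
               paste("REPORTERS", paste(lib$reporter_names, collapse = " "))),
             con)
  for (k in seq_along(lib$coords)) {
    writeLines(sprintf("ROTAMER %d %.12g", k, lib$weights[k]), con)
    writeLines(sprintf("%.6f %.6f %.6f",
                       lib$coords[[k]][, 1], lib$coords[[k]][, 2],
                       lib$coords[[k]][, 3]), con)
  }
  invisible(path)
}

#' Read a rotamer library written by [write_rotamer_library()]
#'
#' @param path library file.
#' @return a `rotamer_library`.
#' @export
read_rotamer_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  field <- function(tag) {
    ln <- grep(paste0("^", tag, " "), lines, value = TRUE)[1]
    strsplit(ln, "[[:space:]]+")[[1]][-1]
  }
  atom_names <- field("ATOMS")
  starts <- grep("^ROTAMER ", lines)
  coords <- list(); weights <- numeric(0)
  for (s in starts) {
    hd <- strsplit(lines[s], "[[:space:]]+")[[1]]
    weights <- c(weights, as.numeric(hd[3]))
    blk <- lines[(s + 1):(s + length(atom_names))]
    m <- do.call(rbind, lapply(strsplit(trimws(blk), "[[:space:]]+"),
                               as.numeric))
    coords[[length(coords) + 1L]] <- m
  }
  rotamer_library(coords = coords, weights = weights,
                  atom_names = atom_names, anchor_names = field("ANCHORS"),
                  reporter_names = field("REPORTERS"))
}

#' Poisson-sampled cavity waters
#'
#' Water oxygen positions are drawn uniformly in an axis-aligned box at
#' the requested number density and rejected within 2.6 Angstrom of any
#' protein atom (hard-sphere water-heavy-atom contact), so the expected
#' count equals density times the accessible volume.
#'
#' @param structure a `structure3d`, or `NULL` for an empty box.
#' @param region list with numeric 3-vectors `min` and `max`, Angstrom.
#' @param number_density waters per cubic Angstrom.
#' @param seed integer seed.
#' @param n_frames number of independent draws.
#' @param exclusion_radius rejection distance around protein atoms,
#'   Angstrom.
#' @return list of n x 3 matrices (class `water_frames`), one per frame.
#' @export
fill_cavity_waters <- function(structure, region, number_density,
                               seed = 1, n_frames = 1L,
                               exclusion_radius = 2.6) {
  lo <- region$min; hi <- region$max
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(hi > lo),
            number_density >= 0)
  vol <- prod(hi - lo)
  pxyz <- if (!is.null(structure)) coords(structure) else
    matrix(numeric(0), 0, 3)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    n <- stats::rpois(1, number_density * vol)
    if (n == 0) return(matrix(numeric(0), 0, 3))
    w <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
    if (nrow(pxyz)) {
      keep <- vapply(seq_len(n), function(i) {
        d2 <- (pxyz[, 1] - w[i, 1])^2 + (pxyz[, 2] - w[i, 2])^2 +
          (pxyz[, 3] - w[i, 3])^2
        min(d2) >= exclusion_radius^2
      }, logical(1))
      w <- w[keep, , drop = FALSE]
    }
    w
  })
  class(frames) <- "water_frames"
  frames
}
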