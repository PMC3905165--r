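#' gatescape: functional-state analyses for MFS transporter conformations
#'
#' Tools to characterise conformations and conformational ensembles of
#' major facilitator superfamily (MFS) transporters: two-gate geometric
#' order parameters and state classification, pore-radius and
#' water-density characterisation of permeation pathways, a
#' finite-difference linearized Poisson-Boltzmann (FD-LPB) landscape of
#' the electrostatic free energy of a solvated proton in an implicit
#' membrane, rotamer-library prediction of DEER spin-spin distance
#' distributions, and Daura conformational clustering.  A synthetic
#' two-domain helical-bundle generator provides test systems with
#' independently tunable cytoplasmic and periplasmic gates.
#'
#' @import bio3d
#' @importFrom stats optim rnorm runif rgamma sd setNames dist approx
#' @importFrom utils read.csv write.csv head tail
#' @name gatescape-package
"_PACKAGE"

# ---------------------------------------------------------------------------
# van der Waals radii
# ---------------------------------------------------------------------------

#' Default van der Waals radii by element
#'
#' Bondi (1964) radii for the common elements of protein structures,
#' with a generic 1.70 A fallback applied by [read_structure()] for
#' elements not in the table.  Units: Angstrom.
#'
#' @format Named numeric vector (element symbol -> radius in Angstrom).
#' @export
vdw_radii_bondi <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90,
  Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39, Fe = 2.00
)

.default_vdw <- 1.70

vdw_for_element <- function(element) {
  r <- unname(vdw_radii_bondi[element])
  r[is.na(r)] <- .default_vdw
  r
}

# Guess the element from a PDB atom name when no element column is present.
element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9'\"*]", "", trimws(nm))
    if (!nzchar(nm)) return("C")
    two <- substr(nm, 1, 2)
    if (two %in% c("CL", "Cl", "BR", "Br", "SE", "Se", "FE", "Fe",
                   "NA", "MG", "ZN", "CA")) {
      # two-letter elements only when the full name is the element itself
      if (nchar(nm) == 2) return(paste0(substr(two, 1, 1),
                                        tolower(substr(two, 2, 2))))
    }
    substr(nm, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Structure and Ensemble containers
# ---------------------------------------------------------------------------

#' Construct a molecular structure
#'
#' A `structure3d` is the basic container of the package: an ordered
#' atom table with residue identity, coordinates (Angstrom), a van der
#' Waals radius per atom and an optional partial charge (elementary
#' charges, default 0).
#'
#' @param atoms data frame with columns `name`, `element`, `resname`,
#'   `resid`, `chain`, `x`, `y`, `z`, and optionally `vdw` and `charge`.
#' @param label free-text identifier.
#' @param anchors optional named list of metadata (used by the synthetic
#'   bundle generator to record its gate anchor residues).
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, label = "", anchors = NULL) {
  req <- c("name", "element", "resname", "resid", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stop("a structure must contain at least one atom")
  atoms$resid <- as.integer(atoms$resid)
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_for_element(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(atoms$vdw <= 0)) stop("van der Waals radii must be positive")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, name) triple: ", key[anyDuplicated(key)])
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, label = label, anchors = anchors)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d atoms, %d residues, chains: %s\n",
              x$label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param x a `structure3d`.
#' @return numeric matrix with one row per atom (Angstrom).
#' @export
coords <- function(x) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates
#'
#' @param x a `structure3d`.
#' @param xyz numeric n x 3 matrix.
#' @return the modified structure.
#' @export
set_coords <- function(x, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(x$atoms) || ncol(xyz) != 3L)
    stop("coordinate matrix must be ", nrow(x$atoms), " x 3")
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' Construct a conformational ensemble
#'
#' An ordered sequence of conformations sharing one topology: a
#' trajectory at desk scale.
#'
#' @param topology a `structure3d` giving atom identities.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param times optional per-frame times in ps.
#' @return object of class `ensemble3d`.
#' @export
ensemble3d <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "structure3d"))
  if (length(frames) < 1L) stop("an ensemble needs at least one frame")
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != n || ncol(frames[[i]]) != 3L)
      stop("frame ", i, " is not ", n, " x 3")
    dimnames(frames[[i]]) <- NULL
  }
  out <- list(topology = topology, frames = frames, times = times)
  class(out) <- "ensemble3d"
  out
}

#' @export
print.ensemble3d <- function(x, ...) {
  cat(sprintf("ensemble3d: %d frames x %d atoms ('%s')\n",
              length(x$frames), nrow(x$topology$atoms), x$topology$label))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x an `ensemble3d`.
#' @export
n_frames <- function(x) length(x$frames)

#' Extract one frame of an ensemble as a structure
#'
#' @param x an `ensemble3d`.
#' @param i frame index.
#' @return a `structure3d` with the topology's identities and frame
#'   `i`'s coordinates.
#' @export
get_frame <- function(x, i) {
  stopifnot(i >= 1, i <= length(x$frames))
  set_coords(x$topology, x$frames[[i]])
}

#' Membrane frame convention
#'
#' The membrane normal is +z with the midplane at z = 0 unless
#' overridden; analyses interpret coordinates in this frame.
#'
#' @param normal_axis one of "x", "y", "z".
#' @param midplane_offset position of the membrane midplane along the
#'   normal axis, Angstrom.
#' @return object of class `membrane_frame`.
#' @export
membrane_frame <- function(normal_axis = "z", midplane_offset = 0) {
  normal_axis <- match.arg(normal_axis, c("x", "y", "z"))
  structure(list(normal_axis = normal_axis,
                 midplane_offset = midplane_offset),
            class = "membrane_frame")
}

# Signed position along the membrane normal, relative to the midplane.
membrane_coord <- function(xyz, membrane = membrane_frame()) {
  ax <- match(membrane$normal_axis, c("x", "y", "z"))
  xyz[, ax] - membrane$midplane_offset
}

# ---------------------------------------------------------------------------
# PDB reading / writing (via bio3d)
# ---------------------------------------------------------------------------

validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(sel))
    stop("no ATOM/HETATM records in '", path, "'")
  for (i in sel) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, " of '", path,
           "': record too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed ATOM/HETATM record at line ", i, " of '", path,
           "': unparseable coordinates")
  }
  invisible(sel)
}

bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  element <- a$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  if (any(bad)) element[bad] <- element_from_name(a$elety[bad])
  element <- trimws(element)
  # normalize case, e.g. "CL" -> "Cl"
  element <- ifelse(nchar(element) == 2,
                    paste0(substr(element, 1, 1),
                           tolower(substr(element, 2, 2))),
                    toupper(element))
  chain <- a$chain
  chain[is.na(chain)] <- ""
  data.frame(name = trimws(a$elety), element = element,
             resname = trimws(a$resid), resid = a$resno, chain = chain,
             x = a$x, y = a$y, z = a$z,
             vdw = vdw_for_element(element), charge = 0,
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Atoms are returned in file order.  When the file holds several
#' MODEL blocks, only the first model is used and a warning is
#' emitted.  Van der Waals radii are assigned from
#' [vdw_radii_bondi] keyed on the element (PDB element column when
#' present, otherwise inferred from the atom name).
#'
#' @param path PDB file.
#' @param label structure label; defaults to the file name.
#' @return a `structure3d`.
#' @export
read_structure <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- if (is.null(pdb$xyz)) 1L else nrow(as.matrix(pdb$xyz))
  if (!is.null(nmod) && nmod > 1L)
    warning("'", path, "' holds ", nmod,
            " models; using the first model only")
  structure3d(bio3d_to_atoms(pdb), label = label)
}

#' Read a multi-model PDB file as an ensemble
#'
#' One frame per MODEL block; a file without MODEL records yields a
#' single-frame ensemble identical to [read_structure()].
#'
#' @param path multi-model PDB file.
#' @param label ensemble label.
#' @return an `ensemble3d`.
#' @export
read_ensemble <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  # enforce identical atom counts across MODEL blocks before delegating
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1L) {
    counts <- integer(length(model_starts))
    bounds <- c(model_starts, length(lines) + 1L)
    for (k in seq_along(model_starts)) {
      blk <- rec[bounds[k]:(bounds[k + 1L] - 1L)]
      counts[k] <- sum(blk %in% c("ATOM  ", "HETATM"))
    }
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop("model ", bad, " of '", path, "' has ", counts[bad],
           " atoms where model 1 has ", counts[1L])
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          verbose = FALSE))
  xyz <- as.matrix(pdb$xyz)
  topo <- structure3d(bio3d_to_atoms(pdb), label = label)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  ensemble3d(topo, frames)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM records (standard-conformant PDB).
#'
#' @param x a `structure3d`.
#' @param path output file.
#' @export
write_structure <- function(x, path) {
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(x))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resid, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = ifelse(nzchar(a$chain), a$chain, " "),
                   elesy = a$element)
  invisible(path)
}

#' Write an ensemble to a multi-model PDB file
#'
#' @param x an `ensemble3d`.
#' @param path output file.
#' @export
write_ensemble <- function(x, path) {
  a <- x$topology$atoms
  xyz <- do.call(rbind, lapply(x$frames, function(f) as.numeric(t(f))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(a)),
                   resno = a$resid, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = ifelse(nzchar(a$chain), a$chain, " "),
                   elesy = a$element)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PQR (pdb2pqr whitespace dialect)
# ---------------------------------------------------------------------------

#' Read a PQR file
#'
#' Whitespace-delimited pdb2pqr dialect: `ATOM serial name resname
#' [chain] resid x y z charge radius`.  Charge and radius populate the
#' atom table's `charge` and `vdw` columns.
#'
#' @param path PQR file.
#' @param label structure label.
#' @return a `structure3d`.
#' @export
read_pqr <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  if (!any(keep)) stop("no ATOM/HETATM records in '", path, "'")
  rows <- lapply(which(keep), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) == 10L) {
      # either a chain-less record or a chained record with a missing
      # trailing column; a chain-less record has an integer resid here
      if (!grepl("^-?[0-9]+$", tok[5]))
        stop("PQR record at line ", i, " of '", path,
             "' has 10 fields with a non-numeric residue field: ",
             "missing charge/radius column?")
      tok <- append(tok, "", after = 4L)
    }
    if (length(tok) != 11L)
      stop("PQR record at line ", i, " of '", path, "' has ",
           length(tok), " fields; expected 10 or 11 ",
           "(missing charge/radius column?)")
    num <- suppressWarnings(as.numeric(tok[7:11]))
    if (any(is.na(num)))
      stop("PQR record at line ", i, " of '", path,
           "': unparseable numeric field")
    data.frame(name = tok[3], resname = tok[4], chain = tok[5],
               resid = as.integer(tok[6]),
               x = num[1], y = num[2], z = num[3],
               charge = num[4], vdw = num[5], stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  atoms$element <- element_from_name(atoms$name)
  structure3d(atoms[, c("name", "element", "resname", "resid", "chain",
                        "x", "y", "z", "vdw", "charge")], label = label)
}

#' Write a PQR file
#'
#' @param x a `structure3d` (its `charge` and `vdw` columns are
#'   written as the PQR charge and radius fields).
#' @param path output file.
#' @export
write_pqr <- function(x, path) {
  a <- x$atoms
  chain <- ifelse(nzchar(a$chain), a$chain, "X")
  lines <- sprintf("ATOM %6d %-4s %-4s %s %4d %10.4f %10.4f %10.4f %8.4f %7.4f",
                   seq_len(nrow(a)), a$name, a$resname, chain, a$resid,
                   a$x, a$y, a$z, a$charge, a$vdw)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom selection
# ---------------------------------------------------------------------------

#' Select atoms by name, residue, residue name and chain
#'
#' Conjunctive across fields, disjunctive within a field's values; a
#' `NULL` field places no constraint, so an empty query selects all
#' atoms.  Indices are returned in atom order.
#'
#' @param x a `structure3d` or an atom data frame.
#' @param names,resids,resnames,chains optional value vectors.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(x, names = NULL, resids = NULL,
                         resnames = NULL, chains = NULL) {
  a <- if (inherits(x, "structure3d")) x$atoms else x
  keep <- rep(TRUE, nrow(a))
  if (!is.null(names)) keep <- keep & a$name %in% names
  if (!is.null(resids)) keep <- keep & a$resid %in% resids
  if (!is.null(resnames)) keep <- keep & a$resname %in% resnames
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  which(keep)
}
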