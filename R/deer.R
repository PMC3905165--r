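# Prediction of DEER spin-spin distance distributions by
# rotamer-library convolution: rigid-body attachment of a weighted
# spin-label rotamer library onto labelled sites, steric clash
# filtering against the protein, and weighted pair-distance
# histogramming over single structures and ensembles.

#' Spin-label site
#'
#' @param chain,resid the labelled residue.
#' @param clash_cutoff steric clash distance, Angstrom (default 2.0;
#'   1.5 for tightly packed sites).
#' @return object of class `label_site`.
#' @export
label_site <- function(chain, resid, clash_cutoff = 2.0) {
  stopifnot(clash_cutoff > 0)
  structure(list(chain = chain, resid = resid,
                 clash_cutoff = clash_cutoff), class = "label_site")
}

# right-handed orthonormal frame from the three backbone anchors:
# origin at CA, x toward N, z along x cross (C - CA)
anchor_frame <- function(pN, pCA, pC) {
  xhat <- pN - pCA; xhat <- xhat / sqrt(sum(xhat^2))
  v <- pC - pCA
  zhat <- c(xhat[2] * v[3] - xhat[3] * v[2],
            xhat[3] * v[1] - xhat[1] * v[3],
            xhat[1] * v[2] - xhat[2] * v[1])
  nz <- sqrt(sum(zhat^2))
  if (nz < 1e-8) stop("anchor atoms are collinear; frame undefined")
  zhat <- zhat / nz
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  list(origin = pCA, R = cbind(xhat, yhat, zhat))
}

#' Attach a rotamer library to a labelled site
#'
#' Rigid-body transform of each rotamer from the canonical side-chain
#' frame onto the site's backbone anchor triad (N, CA, C by default).
#' Library weights are carried over unchanged; clash filtering is a
#' separate step ([clash_filter()]).
#'
#' @param frame a `structure3d` conformation.
#' @param site a [label_site()].
#' @param library a `rotamer_library`.
#' @return object of class `placed_rotamers`: list with `site`,
#'   `rotamer_coords` (list of m x 3 matrices in the structure frame),
#'   `weights`, `spin_positions` (one midpoint of the reporter atoms
#'   per rotamer) and `atom_names`.
#' @export
attach_rotamers <- function(frame, site, library) {
  stopifnot(inherits(site, "label_site"),
            inherits(library, "rotamer_library"))
  anchor_idx <- vapply(library$anchor_names, function(nm) {
    i <- select_atoms(frame, names = nm, resids = site$resid,
                      chains = site$chain)
    if (length(i) != 1L) NA_integer_ else i
  }, integer(1))
  if (any(is.na(anchor_idx)))
    stop("missing anchor atom(s) ",
         paste(library$anchor_names[is.na(anchor_idx)], collapse = ", "),
         " at site ", site$chain, ":", site$resid)
  xyz <- coords(frame)
  fr <- anchor_frame(xyz[anchor_idx[1], ], xyz[anchor_idx[2], ],
                     xyz[anchor_idx[3], ])
  placed <- lapply(library$coords, function(m) {
    sweep(m %*% t(fr$R), 2, fr$origin, "+")
  })
  rep_idx <- match(library$reporter_names, library$atom_names)
  spin <- t(vapply(placed, function(m) {
    (m[rep_idx[1], ] + m[rep_idx[2], ]) / 2
  }, numeric(3)))
  structure(list(site = site, rotamer_coords = placed,
                 weights = library$weights, spin_positions = spin,
                 atom_names = library$atom_names),
            class = "placed_rotamers")
}

#' Discard rotamers that sterically clash with the protein
#'
#' A rotamer is removed when any of its atoms lies within the site's
#' clash cutoff of any non-excluded protein heavy atom (hydrogens are
#' ignored); surviving weights are renormalized.  The excluded index
#' list must cover at least the labelled residue's own side chain,
#' which is conceptually replaced by the label.
#'
#' @param placed a `placed_rotamers`.
#' @param frame the `structure3d` the rotamers were placed on.
#' @param excluded atom indices exempt from the clash test.
#' @return a `placed_rotamers` with the clashing rotamers removed;
#'   when nothing survives, an empty result with attribute
#'   `empty = TRUE` (not an error).
#' @export
clash_filter <- function(placed, frame, excluded = integer(0)) {
  stopifnot(inherits(placed, "placed_rotamers"))
  heavy <- which(frame$atoms$element != "H")
  test_idx <- setdiff(heavy, excluded)
  xyz <- coords(frame)[test_idx, , drop = FALSE]
  cutoff2 <- placed$site$clash_cutoff^2
  keep <- vapply(placed$rotamer_coords, function(m) {
    if (!nrow(xyz)) return(TRUE)
    for (a in seq_len(nrow(m))) {
      d2 <- (xyz[, 1] - m[a, 1])^2 + (xyz[, 2] - m[a, 2])^2 +
        (xyz[, 3] - m[a, 3])^2
      if (min(d2) < cutoff2) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- placed
  out$rotamer_coords <- placed$rotamer_coords[keep]
  out$spin_positions <- placed$spin_positions[keep, , drop = FALSE]
  w <- placed$weights[keep]
  out$weights <- if (length(w)) w / sum(w) else numeric(0)
  if (!length(w)) attr(out, "empty") <- TRUE
  out
}

#' Default excluded atoms for a labelled site
#'
#' The labelled residue's own atoms (its side chain is conceptually
#' mutated to the spin label; backbone proximity is tolerated too, as
#' the label is bonded there).
#'
#' @param frame a `structure3d`.
#' @param site a [label_site()].
#' @return integer atom indices.
#' @export
site_excluded_atoms <- function(frame, site) {
  select_atoms(frame, resids = site$resid, chains = site$chain)
}

#' Distance-distribution bin edges
#'
#' @param from,to,by bin range and width in Angstrom (default 0-80 in
#'   1 Angstrom bins, the usual DEER display range).
#' @export
deer_bins <- function(from = 0, to = 80, by = 1) seq(from, to, by = by)

#' Spin-spin distance distribution of two placed rotamer sets
#'
#' Every rotamer pair (i, j) contributes its spin-spin distance with
#' weight wA_i x wB_j; the weights are histogrammed over the bins.
#' Total mass is 1 whenever both sites have surviving rotamers.
#'
#' @param placedA,placedB `placed_rotamers` (post clash filter).
#' @param bins bin edges in Angstrom (see [deer_bins()]).
#' @return object of class `distance_distribution`: list with
#'   `bin_edges`, `probabilities` (length `length(bins) - 1`) and
#'   `empty` flag.
#' @export
pair_distribution <- function(placedA, placedB, bins = deer_bins()) {
  nA <- length(placedA$weights); nB <- length(placedB$weights)
  probs <- numeric(length(bins) - 1L)
  if (nA == 0L || nB == 0L) {
    return(structure(list(bin_edges = bins, probabilities = probs,
                          empty = TRUE), class = "distance_distribution"))
  }
  A <- placedA$spin_positions; B <- placedB$spin_positions
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  w <- outer(placedA$weights, placedB$weights)
  bin <- findInterval(d, bins, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= length(probs)
  for (k in which(inside)) probs[bin[k]] <- probs[bin[k]] + w[k]
  # renormalize over in-range mass so the distribution sums to 1
  tot <- sum(probs)
  if (tot > 0) probs <- probs / tot
  structure(list(bin_edges = bins, probabilities = probs, empty = FALSE),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("distance_distribution: empty (no surviving rotamers)\n")
  } else {
    mid <- (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2
    m <- sum(mid * x$probabilities)
    cat(sprintf("distance_distribution: mean %.2f A, mass %.4f\n",
                m, sum(x$probabilities)))
  }
  invisible(x)
}

#' Mean of a distance distribution
#' @param x a `distance_distribution`.
#' @return mean spin-spin distance, Angstrom (NA when empty).
#' @export
distribution_mean <- function(x) {
  if (isTRUE(x$empty)) return(NA_real_)
  mid <- (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2
  sum(mid * x$probabilities)
}

# place + filter both sites on one conformation
place_pair <- function(frame, siteA, siteB, library) {
  pA <- clash_filter(attach_rotamers(frame, siteA, library), frame,
                     excluded = c(site_excluded_atoms(frame, siteA),
                                  site_excluded_atoms(frame, siteB)))
  pB <- clash_filter(attach_rotamers(frame, siteB, library), frame,
                     excluded = c(site_excluded_atoms(frame, siteA),
                                  site_excluded_atoms(frame, siteB)))
  list(A = pA, B = pB)
}

#' Spin-spin distance distribution for a single conformation
#'
#' Attaches the library to both sites, clash-filters each against the
#' protein (both labelled residues excluded) and histograms the
#' weighted pair distances.
#'
#' @param frame a `structure3d`.
#' @param siteA,siteB [label_site()] objects.
#' @param library a `rotamer_library`.
#' @param bins bin edges, Angstrom.
#' @return a `distance_distribution`.
#' @export
structure_distribution <- function(frame, siteA, siteB, library,
                                   bins = deer_bins()) {
  pl <- place_pair(frame, siteA, siteB, library)
  pair_distribution(pl$A, pl$B, bins)
}

#' Ensemble-averaged spin-spin distance distribution
#'
#' Per-frame distributions averaged with equal frame weight; frames
#' where either site loses all rotamers are skipped and counted in the
#' `skipped_frames` attribute.
#'
#' @param ensemble an `ensemble3d`.
#' @param siteA,siteB [label_site()] objects.
#' @param library a `rotamer_library`.
#' @param bins bin edges, Angstrom.
#' @param stride analyse every `stride`-th frame.
#' @return a `distance_distribution` (empty-flagged when every frame
#'   is empty).
#' @export
ensemble_distribution <- function(ensemble, siteA, siteB, library,
                                  bins = deer_bins(), stride = 1L) {
  stopifnot(inherits(ensemble, "ensemble3d"))
  idx <- seq(1L, n_frames(ensemble), by = stride)
  acc <- numeric(length(bins) - 1L)
  used <- 0L; skipped <- 0L
  for (i in idx) {
    d <- structure_distribution(get_frame(ensemble, i), siteA, siteB,
                                library, bins)
    if (isTRUE(d$empty)) { skipped <- skipped + 1L; next }
    acc <- acc + d$probabilities
    used <- used + 1L
  }
  if (used == 0L) {
    out <- structure(list(bin_edges = bins, probabilities = acc,
                          empty = TRUE), class = "distance_distribution")
  } else {
    out <- structure(list(bin_edges = bins, probabilities = acc / used,
                          empty = FALSE), class = "distance_distribution")
  }
  attr(out, "skipped_frames") <- skipped
  out
}

#' Write a distance distribution as tab-separated text
#'
#' Columns: bin centre (Angstrom), probability.
#'
#' @param x a `distance_distribution`.
#' @param path output file.
#' @export
write_distribution <- function(x, path) {
  mid <- (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2
  utils::write.table(data.frame(bin_center = mid,
                                probability = x$probabilities),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
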