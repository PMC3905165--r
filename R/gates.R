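# Two-gate geometric order parameters for MFS transporters: the
# cytoplasmic gate is tracked by a fixed Calpha-Calpha residue pair on
# helices TM4/TM10, the periplasmic gate by a pair on TM1/TM7.  Pairs
# are frozen from a reference structure (closest inter-helix contact)
# and then tracked across frames.

#' Helix residue range
#'
#' @param chain chain identifier.
#' @param first_resid,last_resid inclusive residue range.
#' @return object of class `helix_range`.
#' @export
helix_range <- function(chain, first_resid, last_resid) {
  stopifnot(first_resid <= last_resid)
  structure(list(chain = chain, first_resid = first_resid,
                 last_resid = last_resid), class = "helix_range")
}

#' Fixed gate anchor residue pair
#'
#' @param gate `"cytoplasmic"` or `"periplasmic"`.
#' @param chainA,residA,chainB,residB the two anchor residues.
#' @param derived_from label of the reference structure the pair was
#'   frozen from.
#' @return object of class `gate_pair`.
#' @export
gate_pair <- function(gate, chainA, residA, chainB, residB,
                      derived_from = "") {
  gate <- match.arg(gate, c("cytoplasmic", "periplasmic"))
  if (identical(chainA, chainB) && residA == residB)
    stop("gate anchors must be two distinct residues")
  structure(list(gate = gate, chainA = chainA, residA = residA,
                 chainB = chainB, residB = residB,
                 derived_from = derived_from), class = "gate_pair")
}

ca_index <- function(x, chain, resid) {
  i <- select_atoms(x, names = "CA", resids = resid, chains = chain)
  if (length(i) != 1L) return(NA_integer_)
  i
}

#' Derive a gate pair from a reference structure
#'
#' Computes the full Calpha-Calpha cross-distance matrix between two
#' helices and freezes the closest-contact residue pair as the gate's
#' order-parameter anchors.  Ties are broken by lower residue number in
#' helix A, then in helix B.
#'
#' @param reference a `structure3d`.
#' @param helixA,helixB [helix_range()] objects.
#' @param gate `"cytoplasmic"` or `"periplasmic"`.
#' @return a `gate_pair`; attribute `distance` carries the reference
#'   closest-contact distance in Angstrom.
#' @export
derive_gate_pair <- function(reference, helixA, helixB, gate) {
  getCA <- function(h) {
    resids <- h$first_resid:h$last_resid
    idx <- vapply(resids, function(r) {
      i <- select_atoms(reference, names = "CA", resids = r,
                        chains = h$chain)
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    present <- !is.na(idx)
    if (!any(present))
      stop("no Calpha atoms in helix range ", h$chain, ":",
           h$first_resid, "-", h$last_resid, " (missing residues: ",
           paste(resids[!present], collapse = ", "), ")")
    list(resids = resids[present], idx = idx[present])
  }
  A <- getCA(helixA); B <- getCA(helixB)
  xyz <- coords(reference)
  pa <- xyz[A$idx, , drop = FALSE]; pb <- xyz[B$idx, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  # tie-break: iterate in increasing resid order, strict improvement only
  best <- c(NA, NA); bestd <- Inf
  oa <- order(A$resids); ob <- order(B$resids)
  for (i in oa) for (j in ob) {
    if (d2[i, j] < bestd - 1e-12) { bestd <- d2[i, j]; best <- c(i, j) }
  }
  gp <- gate_pair(gate, helixA$chain, A$resids[best[1]],
                  helixB$chain, B$resids[best[2]],
                  derived_from = reference$label)
  attr(gp, "distance") <- sqrt(max(bestd, 0))
  gp
}

#' Gate order parameter for one conformation
#'
#' Euclidean Calpha-Calpha distance between the pair's anchors.
#'
#' @param frame a `structure3d`.
#' @param pair a `gate_pair`.
#' @return distance in Angstrom.
#' @export
gate_distance <- function(frame, pair) {
  ia <- ca_index(frame, pair$chainA, pair$residA)
  ib <- ca_index(frame, pair$chainB, pair$residB)
  if (is.na(ia) || is.na(ib)) {
    miss <- c(if (is.na(ia)) paste0(pair$chainA, ":", pair$residA),
              if (is.na(ib)) paste0(pair$chainB, ":", pair$residB))
    stop("anchor Calpha missing in frame: ", paste(miss, collapse = ", "))
  }
  xyz <- coords(frame)
  sqrt(sum((xyz[ia, ] - xyz[ib, ])^2))
}

#' Per-frame order-parameter trace of an ensemble
#'
#' @param ensemble an `ensemble3d`.
#' @param cyt_pair,peri_pair `gate_pair` objects for the cytoplasmic
#'   and periplasmic gates.
#' @param thresholds a [state_thresholds()]; each frame is also
#'   classified.
#' @return data frame with columns `frame`, `d_cyt`, `d_peri`, `state`.
#' @export
order_parameter_trace <- function(ensemble, cyt_pair, peri_pair,
                                  thresholds = state_thresholds()) {
  stopifnot(inherits(ensemble, "ensemble3d"))
  topo <- ensemble$topology
  ia <- ca_index(topo, cyt_pair$chainA, cyt_pair$residA)
  ib <- ca_index(topo, cyt_pair$chainB, cyt_pair$residB)
  ja <- ca_index(topo, peri_pair$chainA, peri_pair$residA)
  jb <- ca_index(topo, peri_pair$chainB, peri_pair$residB)
  if (any(is.na(c(ia, ib, ja, jb))))
    stop("gate anchor Calpha missing from ensemble topology")
  d_cyt <- vapply(ensemble$frames,
                  function(f) sqrt(sum((f[ia, ] - f[ib, ])^2)), numeric(1))
  d_peri <- vapply(ensemble$frames,
                   function(f) sqrt(sum((f[ja, ] - f[jb, ])^2)), numeric(1))
  data.frame(frame = seq_along(ensemble$frames), d_cyt = d_cyt,
             d_peri = d_peri,
             state = classify_state(d_cyt, d_peri, thresholds),
             stringsAsFactors = FALSE)
}

#' Occlusion thresholds on the gate order parameters
#'
#' Defaults follow the occluded-state observation window: cytoplasmic
#' order parameter below 13 Angstrom and periplasmic below 8 Angstrom.
#'
#' @param cyt_occluded_max,peri_occluded_max thresholds in Angstrom.
#' @return object of class `state_thresholds`.
#' @export
state_thresholds <- function(cyt_occluded_max = 13,
                             peri_occluded_max = 8) {
  stopifnot(cyt_occluded_max > 0, peri_occluded_max > 0)
  structure(list(cyt_occluded_max = cyt_occluded_max,
                 peri_occluded_max = peri_occluded_max),
            class = "state_thresholds")
}

#' Classify a conformational state from the two order parameters
#'
#' Quadrant logic: `occluded` when both gates are below their
#' thresholds, `cytoplasmic_open` / `periplasmic_open` when exactly the
#' corresponding gate is at or above threshold, and `leak` when both
#' are — a state the alternating-access mechanism must avoid, included
#' so the classifier is total.
#'
#' @param d_cyt,d_peri order parameters in Angstrom (vectorized).
#' @param thresholds a [state_thresholds()].
#' @return character vector of state labels.
#' @export
classify_state <- function(d_cyt, d_peri, thresholds = state_thresholds()) {
  stopifnot(all(d_cyt >= 0), all(d_peri >= 0))
  co <- d_cyt >= thresholds$cyt_occluded_max
  po <- d_peri >= thresholds$peri_occluded_max
  out <- character(length(co))
  out[!co & !po] <- "occluded"
  out[co & !po] <- "cytoplasmic_open"
  out[!co & po] <- "periplasmic_open"
  out[co & po] <- "leak"
  out
}

#' Occupancy summary of order-parameter space
#'
#' For each labelled trace: the enclosing (d_cyt, d_peri) bounding box;
#' plus a pooled 2D histogram whose counts sum to the total number of
#' frames.
#'
#' @param traces named list of data frames with columns `d_cyt`,
#'   `d_peri` (as from [order_parameter_trace()]).
#' @param nbins number of histogram bins per axis.
#' @return list with `boxes` (data frame) and `histogram` (list with
#'   `breaks_cyt`, `breaks_peri`, `counts`).
#' @export
state_space_summary <- function(traces, nbins = 20L) {
  stopifnot(length(traces) >= 1L)
  if (is.null(names(traces)))
    names(traces) <- paste0("series", seq_along(traces))
  boxes <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    data.frame(label = nm, n = nrow(tr),
               cyt_min = min(tr$d_cyt), cyt_max = max(tr$d_cyt),
               peri_min = min(tr$d_peri), peri_max = max(tr$d_peri),
               stringsAsFactors = FALSE)
  }))
  all_cyt <- unlist(lapply(traces, `[[`, "d_cyt"))
  all_peri <- unlist(lapply(traces, `[[`, "d_peri"))
  pad <- 1e-9
  bx <- seq(min(all_cyt) - pad, max(all_cyt) + pad, length.out = nbins + 1L)
  by <- seq(min(all_peri) - pad, max(all_peri) + pad, length.out = nbins + 1L)
  ix <- pmin(pmax(findInterval(all_cyt, bx), 1L), nbins)
  iy <- pmin(pmax(findInterval(all_peri, by), 1L), nbins)
  counts <- matrix(0L, nbins, nbins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  list(boxes = boxes,
       histogram = list(breaks_cyt = bx, breaks_peri = by, counts = counts))
}

#' Gate pairs of a synthetic bundle
#'
#' Reads the anchor residues recorded by [make_bundle()] and returns
#' the cytoplasmic and periplasmic `gate_pair` objects.
#'
#' @param bundle a `structure3d` produced by [make_bundle()].
#' @return list with elements `cyt` and `peri`.
#' @export
bundle_gate_pairs <- function(bundle) {
  an <- bundle$anchors
  if (is.null(an)) stop("structure carries no recorded gate anchors")
  list(cyt = gate_pair("cytoplasmic",
                       an$cyt_A$chain, an$cyt_A$resid,
                       an$cyt_B$chain, an$cyt_B$resid,
                       derived_from = bundle$label),
       peri = gate_pair("periplasmic",
                        an$peri_A$chain, an$peri_A$resid,
                        an$peri_B$chain, an$peri_B$resid,
                        derived_from = bundle$label))
}

#' Bundled gate-defining residue pairs for 12 MFS transporters
#'
#' The closest-contact Calpha pairs on helices TM4/TM10 (cytoplasmic
#' gate) and TM1/TM7 (periplasmic gate) for EmrD, FucP, GlpT, LacY,
#' NarU, NarK, PepT_So, PepT_St, PiPT, POT, XylE and YajR, as shipped
#' in `inst/extdata/mfs_gate_pairs.csv`.  Residue numbering follows the
#' deposited structures (author numbering); chains are not recorded in
#' the source table and default to the first protein chain.
#'
#' @return data frame with columns `transporter`, `gate`, `helices`,
#'   `residA`, `resnameA`, `residB`, `resnameB`.
#' @export
mfs_gate_table <- function() {
  read.csv(system.file("extdata", "mfs_gate_pairs.csv",
                       package = "gatescape"),
           stringsAsFactors = FALSE)
}

#' Bundled approximate LacY transmembrane helix ranges
#'
#' Reconstructed from topology annotations of the cytoplasmic-open
#' LacY crystal structure; approximate and intended to be overridden
#' when authoritative helix definitions are available.
#'
#' @return data frame with columns `helix`, `first_resid`, `last_resid`,
#'   `note`.
#' @export
lacy_helix_table <- function() {
  read.csv(system.file("extdata", "lacy_helices.csv",
                       package = "gatescape"),
           stringsAsFactors = FALSE)
}
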