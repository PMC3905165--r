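# Ensemble analysis: optimal superposition RMSD, Daura conformational
# clustering and residue-interaction (salt-bridge) distance traces.

# Kabsch: rotation R such that B %*% R best fits A (rows are points,
# both centred).
kabsch_rotation <- function(A, B) {
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Minimal RMSD between two coordinate sets after rigid superposition
#'
#' Least-squares rotation plus translation (Kabsch), unit weights.
#'
#' @param A,B n x 3 coordinate matrices, Angstrom.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3L, ncol(B) == 3L)
  if (nrow(A) < 3L)
    stop("superposition needs at least 3 atoms (rotation underdetermined)")
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  R <- kabsch_rotation(A0, B0)
  sqrt(mean(rowSums((B0 %*% R - A0)^2)))
}

rmsd_raw <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Pairwise RMSD matrix over an ensemble
#'
#' @param ensemble an `ensemble3d`.
#' @param selection atom indices entering the RMSD (default: all atoms).
#' @param superpose superpose each pair optimally (rigid least squares)
#'   before measuring; raw coordinates otherwise.
#' @return symmetric matrix of RMSD values in nm (zero diagonal).
#' @export
pairwise_rmsd <- function(ensemble, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(ensemble, "ensemble3d"))
  if (is.null(selection)) selection <- seq_len(nrow(ensemble$topology$atoms))
  if (length(selection) < 1L) stop("selection must be non-empty")
  if (superpose && length(selection) < 3L)
    stop("superposition needs at least 3 atoms (rotation underdetermined)")
  fr <- lapply(ensemble$frames, function(f) f[selection, , drop = FALSE])
  n <- length(fr)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- if (superpose) superpose_rmsd(fr[[i]], fr[[j]])
         else rmsd_raw(fr[[i]], fr[[j]])
    m[i, j] <- m[j, i] <- r / 10  # Angstrom -> nm
  }
  m
}

#' Daura conformational clustering
#'
#' Greedy neighbour-count clustering: the frame with the most
#' neighbours within `cutoff` (ties: lowest index) becomes a cluster
#' centre; it and its neighbours are removed and the procedure repeats
#' until no frames remain.  Clusters are ordered by decreasing size,
#' ties by lower centre index.
#'
#' @param rmsd symmetric distance matrix in nm with zero diagonal (as
#'   from [pairwise_rmsd()]).
#' @param cutoff neighbour cutoff in nm (default 0.25).
#' @return object of class `cluster_result`: list with `clusters` (each
#'   a list with `center` and `members`, member lists including the
#'   centre) and `cutoff`.
#' @export
daura_cluster <- function(rmsd, cutoff = 0.25) {
  rmsd <- as.matrix(rmsd)
  n <- nrow(rmsd)
  stopifnot(n == ncol(rmsd), all(abs(diag(rmsd)) < 1e-12),
            isTRUE(all.equal(rmsd, t(rmsd), tolerance = 1e-8)))
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining)) {
    sub <- rmsd[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)  # includes self
    center_pos <- which.max(counts)   # first max = lowest index
    members <- remaining[sub[center_pos, ] <= cutoff]
    clusters[[length(clusters) + 1L]] <-
      list(center = remaining[center_pos], members = members)
    remaining <- setdiff(remaining, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  centers <- vapply(clusters, function(cl) cl$center, integer(1))
  ord <- order(-sizes, centers)
  structure(list(clusters = clusters[ord], cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Daura clustering, cutoff %.3g nm: %d cluster(s)\n",
              x$cutoff, length(x$clusters)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d center frame %d, %d member(s)\n",
                i, cl$center, length(cl$members)))
  }
  invisible(x)
}

#' Is a frame part of the dominant cluster?
#'
#' @param result a `cluster_result`.
#' @param frame frame index.
#' @param which currently only `"dominant"` (the largest cluster).
#' @return logical.
#' @export
contains_frame <- function(result, frame, which = "dominant") {
  which <- match.arg(which, "dominant")
  cl <- result$clusters[[1L]]
  frame %in% union(cl$members, cl$center)
}

#' Minimum inter-group distance trace across an ensemble
#'
#' Per frame, the minimum distance over all cross pairs between two
#' atom groups — e.g. the side-chain nitrogens of an arginine against
#' the carboxylate oxygens of a glutamate for a salt-bridge distance.
#'
#' @param ensemble an `ensemble3d`.
#' @param groupA,groupB non-empty atom index vectors.
#' @return numeric per-frame series (Angstrom) with attributes `mean`
#'   and `sd`.
#' @export
residue_min_distance_trace <- function(ensemble, groupA, groupB) {
  stopifnot(inherits(ensemble, "ensemble3d"))
  if (length(groupA) < 1L || length(groupB) < 1L)
    stop("both atom groups must be non-empty")
  na <- nrow(ensemble$topology$atoms)
  if (any(c(groupA, groupB) < 1) || any(c(groupA, groupB) > na))
    stop("atom index out of range")
  series <- vapply(ensemble$frames, function(f) {
    A <- f[groupA, , drop = FALSE]; B <- f[groupB, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  attr(series, "mean") <- mean(series)
  attr(series, "sd") <- if (length(series) > 1L) stats::sd(series) else 0
  series
}

#' Default salt-bridge atom groups for an Arg--Glu pair
#'
#' Arg side-chain nitrogens (NH1, NH2, NE) against Glu carboxylate
#' oxygens (OE1, OE2); the group-minimum distance is the reported
#' interaction distance.
#'
#' @param x a `structure3d`.
#' @param arg_resid,glu_resid residue numbers.
#' @param chain optional chain restriction.
#' @return list with index vectors `arg` and `glu`.
#' @export
salt_bridge_groups <- function(x, arg_resid, glu_resid, chain = NULL) {
  ga <- select_atoms(x, names = c("NH1", "NH2", "NE"), resids = arg_resid,
                     chains = chain)
  gb <- select_atoms(x, names = c("OE1", "OE2"), resids = glu_resid,
                     chains = chain)
  if (!length(ga)) stop("no Arg side-chain nitrogens found for residue ",
                        arg_resid)
  if (!length(gb)) stop("no Glu carboxylate oxygens found for residue ",
                        glu_resid)
  list(arg = ga, glu = gb)
}
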