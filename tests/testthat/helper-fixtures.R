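# Fixture builders and independent oracles shared across the suite.
# All randomness is seeded at the call sites.

# generic point structure: one atom per row of xyz
point_structure <- function(xyz, name = "CA", element = "C",
                            resname = "ALA", resid = NULL, chain = "A",
                            vdw = NULL, charge = 0, label = "fixture") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  atoms <- data.frame(name = rep_len(name, n),
                      element = rep_len(element, n),
                      resname = rep_len(resname, n),
                      resid = if (is.null(resid)) seq_len(n)
                      else rep_len(resid, n),
                      chain = rep_len(chain, n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  if (!is.null(vdw)) atoms$vdw <- rep_len(vdw, n)
  atoms$charge <- rep_len(charge, n)
  structure3d(atoms, label = label)
}

# ring of atoms in the plane z = z0, used as a pore cross-section
ring_structure <- function(n = 12, R = 5, vdw = 1.5, z0 = 0) {
  th <- 2 * pi * seq_len(n) / n
  point_structure(cbind(R * cos(th), R * sin(th), z0), name = "O",
                  element = "O", resname = "HOH", vdw = vdw,
                  label = "ring")
}

# residue with backbone anchors in the canonical label frame:
# CA at origin, N on +x, C in the xy-plane with positive y
canonical_residue <- function(offset = c(0, 0, 0), resid = 1,
                              chain = "A") {
  xyz <- rbind(c(1.46, 0, 0), c(0, 0, 0), c(-0.52, 1.41, 0))
  xyz <- sweep(xyz, 2, offset, "+")
  point_structure(xyz, name = c("N", "CA", "C"),
                  element = c("N", "C", "C"), resid = resid,
                  chain = chain, label = "canonical residue")
}

# rotation matrix about a unit axis
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# independent brute-force closest-contact search (the oracle for
# derive_gate_pair): scans all pairs in residue order
brute_closest_pair <- function(xyzA, residsA, xyzB, residsB) {
  best <- NULL
  for (i in order(residsA)) for (j in order(residsB)) {
    d <- sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
    if (is.null(best) || d < best$d - 1e-12)
      best <- list(residA = residsA[i], residB = residsB[j], d = d)
  }
  best
}

# independent Daura re-implementation (oracle): different code path
# from the package (explicit neighbour lists, repeated scans)
daura_brute <- function(m, cutoff) {
  n <- nrow(m)
  alive <- rep(TRUE, n)
  out <- list()
  while (any(alive)) {
    ids <- which(alive)
    best_center <- NA; best_count <- -1
    for (i in ids) {
      cnt <- sum(m[i, ids] <= cutoff)
      if (cnt > best_count) { best_count <- cnt; best_center <- i }
    }
    members <- ids[m[best_center, ids] <= cutoff]
    out[[length(out) + 1L]] <- list(center = best_center,
                                    members = members)
    alive[members] <- FALSE
  }
  sizes <- vapply(out, function(cl) length(cl$members), integer(1))
  centers <- vapply(out, function(cl) cl$center, integer(1))
  out[order(-sizes, centers)]
}

# independent recursive flood fill (oracle for pathway connectivity)
floodfill_connected <- function(mask, regionA_idx, regionB_idx,
                                connectivity) {
  dims <- dim(mask)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- expand.grid(-1:1, -1:1, -1:1)
    as.matrix(g[rowSums(abs(g)) > 0, ])
  }
  seen <- array(FALSE, dims)
  inB <- array(FALSE, dims)
  inB[regionB_idx[[1]], regionB_idx[[2]], regionB_idx[[3]]] <- TRUE
  stack <- list()
  for (i in regionA_idx[[1]]) for (j in regionA_idx[[2]])
    for (k in regionA_idx[[3]])
      if (mask[i, j, k]) stack[[length(stack) + 1L]] <- c(i, j, k)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (seen[v[1], v[2], v[3]]) next
    seen[v[1], v[2], v[3]] <- TRUE
    if (inB[v[1], v[2], v[3]]) return(TRUE)
    for (o in seq_len(nrow(offs))) {
      w <- v + offs[o, ]
      if (any(w < 1) || any(w > dims)) next
      if (mask[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]])
        stack[[length(stack) + 1L]] <- w
    }
  }
  FALSE
}

# single-rotamer library whose spin sits at a fixed local position
delta_library <- function(local_spin = c(0, 0, 3)) {
  m <- rbind(c(0, 0, 1), local_spin, local_spin)
  rotamer_library(coords = list(m), weights = 1,
                  atom_names = c("SG", "N1", "O1"),
                  reporter_names = c("N1", "O1"))
}
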