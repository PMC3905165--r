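test_that("rotamer attachment is the identity in the canonical frame", {
  res <- canonical_residue()
  lib <- delta_library(local_spin = c(1, 2, 0.5))
  placed <- attach_rotamers(res, label_site("A", 1), lib)
  expect_equal(placed$rotamer_coords[[1]], lib$coords[[1]],
               tolerance = 1e-9)
  expect_equal(as.numeric(placed$spin_positions), c(1, 2, 0.5),
               tolerance = 1e-9)
})

test_that("attachment is rigid-covariant under translation and rotation", {
  lib <- make_rotamer_library(6, seed = 2)
  res <- canonical_residue()
  p0 <- attach_rotamers(res, label_site("A", 1), lib)

  t <- c(4, -2, 7)
  shifted <- set_coords(res, sweep(coords(res), 2, t, "+"))
  p1 <- attach_rotamers(shifted, label_site("A", 1), lib)
  expect_equal(p1$spin_positions,
               sweep(p0$spin_positions, 2, t, "+"), tolerance = 1e-9)

  R <- rotation_matrix(c(2, -1, 1), 0.8)
  rotated <- set_coords(res, coords(res) %*% t(R))
  p2 <- attach_rotamers(rotated, label_site("A", 1), lib)
  expect_equal(p2$spin_positions, p0$spin_positions %*% t(R),
               tolerance = 1e-9)

  noanchor <- structure3d(res$atoms[res$atoms$name != "N", ])
  expect_error(attach_rotamers(noanchor, label_site("A", 1), lib),
               "anchor")
})

test_that("the clash filter applies the cutoff rule and renormalizes", {
  res <- canonical_residue()
  lib <- delta_library(local_spin = c(0, 0, 3))  # atoms at z=1 and z=3
  placed <- attach_rotamers(res, label_site("A", 1, clash_cutoff = 2.0),
                            lib)
  # protein atom 1.9 A from the rotamer atom at (0, 0, 1)
  clasher <- point_structure(matrix(c(1.9, 0, 1), 1, 3), resid = 50,
                             chain = "B", vdw = 1.7)
  frame <- structure3d(rbind(res$atoms, clasher$atoms))
  excl <- site_excluded_atoms(frame, label_site("A", 1))

  p20 <- clash_filter(attach_rotamers(frame, label_site("A", 1, 2.0), lib),
                      frame, excl)
  expect_length(p20$weights, 0L)         # removed at cutoff 2.0
  expect_true(isTRUE(attr(p20, "empty")))

  p15 <- clash_filter(attach_rotamers(frame, label_site("A", 1, 1.5), lib),
                      frame, excl)
  expect_equal(p15$weights, 1)           # kept at cutoff 1.5

  # no protein within reach: weights unchanged
  lib6 <- make_rotamer_library(6, seed = 9)
  pfree <- clash_filter(attach_rotamers(res, label_site("A", 1), lib6),
                        res, site_excluded_atoms(res, label_site("A", 1)))
  expect_equal(pfree$weights, lib6$weights)

  # removing the clashing atom never loses rotamers (monotonicity)
  p_del <- clash_filter(attach_rotamers(res, label_site("A", 1, 2.0), lib),
                        res, site_excluded_atoms(res, label_site("A", 1)))
  expect_gte(length(p_del$weights), length(p20$weights))
})

test_that("pair distributions reproduce hand-computed weighted masses", {
  mk_placed <- function(spins, weights) {
    structure(list(site = label_site("A", 1),
                   rotamer_coords = list(), weights = weights,
                   spin_positions = matrix(spins, ncol = 3,
                                           byrow = TRUE)),
              class = "placed_rotamers")
  }
  # delta case: one rotamer each, 25 A apart
  a <- mk_placed(c(0, 0, 0), 1)
  b <- mk_placed(c(25.0, 0, 0), 1)
  d <- pair_distribution(a, b)
  expect_equal(sum(d$probabilities), 1)
  expect_equal(d$probabilities[26], 1)  # bin [25, 26)

  # 4-term enumeration: distances {20, 20, 30, 30}, equal weights
  a2 <- mk_placed(c(0, 0, 0, 0, 10, 0), c(0.5, 0.5))
  b2 <- mk_placed(c(20.5, 0, 0, 20.5, 10, 0), c(0.5, 0.5))
  # pairs: (a1,b1)=20.5, (a1,b2)~sqrt(20.5^2+100)=22.8, mixed...
  # use a symmetric layout with exact distances instead:
  a2 <- mk_placed(c(0, 0, 0, 0, 0, 0), c(0.5, 0.5))
  b2 <- mk_placed(c(20.5, 0, 0, 30.5, 0, 0), c(0.5, 0.5))
  d2 <- pair_distribution(a2, b2)
  expect_equal(d2$probabilities[21], 0.5, tolerance = 1e-12)
  expect_equal(d2$probabilities[31], 0.5, tolerance = 1e-12)

  # product weights (0.9, 0.1) x (1.0) at distances (20.5, 30.5)
  a3 <- mk_placed(c(0, 0, 0, 10, 0, 0), c(0.9, 0.1))
  b3 <- mk_placed(c(20.5, 0, 0), 1)
  d3 <- pair_distribution(a3, b3)
  expect_equal(d3$probabilities[21], 0.9, tolerance = 1e-12)
  expect_equal(d3$probabilities[11], 0.1, tolerance = 1e-12)

  # empty site: flagged all-zero distribution, not an error
  d0 <- pair_distribution(mk_placed(numeric(0), numeric(0)), b3)
  expect_true(isTRUE(d0$empty))
  expect_true(all(d0$probabilities == 0))
})

test_that("distributions are rigid-invariant and site-symmetric", {
  # offset off the bin edges: same-rotamer pairs sit at exactly the
  # scaffold separation, which must not fall on an edge
  scaffold <- structure3d(rbind(canonical_residue(resid = 1)$atoms,
                                canonical_residue(offset = c(24.35, 0, 0),
                                                  resid = 2)$atoms))
  lib <- make_rotamer_library(8, seed = 4)
  sA <- label_site("A", 1); sB <- label_site("A", 2)
  d0 <- structure_distribution(scaffold, sA, sB, lib)
  expect_lt(abs(sum(d0$probabilities) - 1), 1e-12)

  R <- rotation_matrix(c(1, 1, 0), 1.3)
  moved <- set_coords(scaffold,
                      sweep(coords(scaffold) %*% t(R), 2, c(3, 4, 5), "+"))
  d1 <- structure_distribution(moved, sA, sB, lib)
  expect_equal(d1$probabilities, d0$probabilities, tolerance = 1e-9)

  d2 <- structure_distribution(scaffold, sB, sA, lib)
  expect_equal(d2$probabilities, d0$probabilities, tolerance = 1e-12)
})

test_that("single-rotamer libraries give a unit mass at the known distance", {
  scaffold <- structure3d(rbind(canonical_residue(resid = 1)$atoms,
                                canonical_residue(offset = c(30, 0, 0),
                                                  resid = 2)$atoms))
  lib <- delta_library(local_spin = c(0, 0, 2))
  d <- structure_distribution(scaffold, label_site("A", 1),
                              label_site("A", 2), lib)
  expect_equal(sum(d$probabilities), 1)
  expect_equal(sum(d$probabilities > 0), 1L)
  # spin positions differ only by the scaffold offset -> distance 30
  expect_lt(abs(distribution_mean(d) - 30), 0.5 + 1e-9)  # half a bin
})

test_that("ensemble averaging mixes frames with equal weight", {
  scaffold1 <- structure3d(rbind(canonical_residue(resid = 1)$atoms,
                                 canonical_residue(offset = c(20.5, 0, 0),
                                                   resid = 2)$atoms))
  scaffold2 <- set_coords(scaffold1, {
    xyz <- coords(scaffold1); xyz[4:6, 1] <- xyz[4:6, 1] + 10; xyz
  })
  lib <- delta_library()
  sA <- label_site("A", 1); sB <- label_site("A", 2)

  one <- ensemble3d(scaffold1, list(coords(scaffold1)))
  de <- ensemble_distribution(one, sA, sB, lib)
  ds <- structure_distribution(scaffold1, sA, sB, lib)
  expect_equal(de$probabilities, ds$probabilities)

  two <- ensemble3d(scaffold1, list(coords(scaffold1), coords(scaffold2)))
  d2 <- ensemble_distribution(two, sA, sB, lib)
  expect_equal(d2$probabilities[21], 0.5, tolerance = 1e-12)
  expect_equal(d2$probabilities[31], 0.5, tolerance = 1e-12)

  rigid <- ensemble3d(scaffold1, rep(list(coords(scaffold1)), 5))
  dr <- ensemble_distribution(rigid, sA, sB, lib)
  expect_equal(dr$probabilities, ds$probabilities)
})
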