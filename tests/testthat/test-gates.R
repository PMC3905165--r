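test_that("derive_gate_pair equals exhaustive minimization on random helices", {
  set.seed(101)
  for (rep in 1:25) {
    xyzA <- matrix(rnorm(24, sd = 6), 8, 3)
    xyzB <- matrix(rnorm(24, sd = 6), 8, 3)
    sA <- point_structure(xyzA, resid = 1:8, chain = "A")
    sB <- point_structure(xyzB, resid = 11:18, chain = "B")
    s <- structure3d(rbind(sA$atoms, sB$atoms))
    gp <- derive_gate_pair(s, helix_range("A", 1, 8),
                           helix_range("B", 11, 18), "cytoplasmic")
    oracle <- brute_closest_pair(xyzA, 1:8, xyzB, 11:18)
    expect_equal(gp$residA, oracle$residA)
    expect_equal(gp$residB, oracle$residB)
    expect_equal(attr(gp, "distance"), oracle$d, tolerance = 1e-12)
  }
})

test_that("single-residue ranges give the direct pair and distance", {
  r1 <- canonical_residue(resid = 5, chain = "A")
  r2 <- canonical_residue(offset = c(3, 4, 0), resid = 9, chain = "B")
  s <- structure3d(rbind(r1$atoms, r2$atoms))
  gp <- derive_gate_pair(s, helix_range("A", 5, 5),
                         helix_range("B", 9, 9), "periplasmic")
  expect_equal(gp$residA, 5)
  expect_equal(gp$residB, 9)
  expect_equal(attr(gp, "distance"), 5)  # 3-4-5 triangle
  expect_equal(gate_distance(s, gp), 5)

  expect_error(derive_gate_pair(s, helix_range("A", 100, 110),
                                helix_range("B", 9, 9), "periplasmic"),
               "missing residues")
})

test_that("gate_distance handles coincident anchors and missing atoms", {
  r1 <- canonical_residue(resid = 1, chain = "A")
  r2 <- canonical_residue(offset = c(0, 0, 0.0), resid = 2, chain = "B")
  r2$atoms$x <- r1$atoms$x; r2$atoms$y <- r1$atoms$y
  r2$atoms$z <- r1$atoms$z
  s <- structure3d(rbind(r1$atoms, r2$atoms))
  gp <- gate_pair("cytoplasmic", "A", 1, "B", 2)
  expect_equal(gate_distance(s, gp), 0)
  expect_error(gate_distance(s, gate_pair("cytoplasmic", "A", 1, "B", 99)),
               "missing")
})

test_that("order-parameter traces follow construction and preserve order", {
  b0 <- make_bundle(bundle_spec(gate_cyt = 1, seed = 6))
  b1 <- make_bundle(bundle_spec(gate_cyt = 0, seed = 6))
  gp <- bundle_gate_pairs(b0)
  one <- ensemble3d(b0, list(coords(b0)))
  tr1 <- order_parameter_trace(one, gp$cyt, gp$peri)
  expect_equal(nrow(tr1), 1L)
  expect_equal(tr1$d_cyt, gate_distance(b0, gp$cyt))
  expect_equal(tr1$d_peri, gate_distance(b0, gp$peri))

  closing <- make_transition(b0, b1, 8, noise_sigma = 0, seed = 1)
  tr <- order_parameter_trace(closing, gp$cyt, gp$peri)
  expect_true(all(diff(tr$d_cyt) < 0))

  const <- make_transition(b0, b0, 5, noise_sigma = 0, seed = 1)
  trc <- order_parameter_trace(const, gp$cyt, gp$peri)
  expect_equal(var(trc$d_cyt), 0)
})

test_that("order parameters are invariant under rigid motion", {
  b <- make_bundle(bundle_spec(gate_cyt = 0.4, gate_peri = 0.7, seed = 8))
  gp <- bundle_gate_pairs(b)
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  moved <- set_coords(b, sweep(coords(b) %*% t(R), 2, c(5, -3, 2), "+"))
  expect_equal(gate_distance(moved, gp$cyt), gate_distance(b, gp$cyt),
               tolerance = 1e-9)
  expect_equal(gate_distance(moved, gp$peri), gate_distance(b, gp$peri),
               tolerance = 1e-9)
})

test_that("classify_state partitions the order-parameter plane", {
  thr <- state_thresholds()  # 13 / 8
  expect_equal(classify_state(12, 7, thr), "occluded")
  expect_equal(classify_state(20, 7, thr), "cytoplasmic_open")
  expect_equal(classify_state(12, 12, thr), "periplasmic_open")
  expect_equal(classify_state(20, 12, thr), "leak")
  # exactly one label everywhere, including the threshold boundaries
  set.seed(7)
  d <- cbind(c(runif(200, 0, 30), 13, 13, 0),
             c(runif(200, 0, 20), 8, 0, 8))
  lab <- classify_state(d[, 1], d[, 2], thr)
  expect_true(all(lab %in% c("occluded", "cytoplasmic_open",
                             "periplasmic_open", "leak")))
  expect_false(any(lab == ""))
})

test_that("synthetic bundles land in the four canonical states", {
  gp <- bundle_gate_pairs(make_bundle(bundle_spec(seed = 4)))
  cases <- list(c(0, 0, NA), c(1, 0, NA), c(0, 1, NA), c(1, 1, NA))
  want <- c("occluded", "cytoplasmic_open", "periplasmic_open", "leak")
  for (i in seq_along(cases)) {
    b <- make_bundle(bundle_spec(gate_cyt = cases[[i]][1],
                                 gate_peri = cases[[i]][2], seed = 4))
    st <- classify_state(gate_distance(b, gp$cyt),
                         gate_distance(b, gp$peri))
    expect_equal(st, want[i])
  }
})

test_that("state-space summaries enclose their series and count all frames", {
  tr1 <- data.frame(d_cyt = c(5, 5), d_peri = c(3, 3))
  tr2 <- data.frame(d_cyt = runif(40, 15, 20), d_peri = runif(40, 9, 12))
  sm <- state_space_summary(list(occ = tr1, open = tr2), nbins = 10)
  expect_equal(sm$boxes$cyt_min[1], 5)
  expect_equal(sm$boxes$cyt_max[1], 5)  # degenerate zero-area box
  expect_true(sm$boxes$cyt_min[2] >= 15 && sm$boxes$cyt_max[2] <= 20)
  # disjoint clusters give disjoint boxes
  expect_lt(sm$boxes$cyt_max[1], sm$boxes$cyt_min[2])
  expect_equal(sum(sm$histogram$counts), 42L)
})

test_that("the bundled MFS gate table carries both gates for 12 transporters", {
  tab <- mfs_gate_table()
  expect_equal(nrow(tab), 24L)
  expect_setequal(unique(tab$gate), c("cytoplasmic", "periplasmic"))
  expect_equal(length(unique(tab$transporter)), 12L)
  lacy <- tab[tab$transporter == "LacY", ]
  expect_setequal(lacy$residA, c(126, 32))
  helices <- lacy_helix_table()
  expect_setequal(helices$helix, c("TM1", "TM4", "TM7", "TM10"))
  expect_true(all(helices$first_resid <= helices$last_resid))
})
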