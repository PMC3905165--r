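test_that("bundle generation is deterministic and gates are independent", {
  a <- make_bundle(bundle_spec(gate_cyt = 0.3, gate_peri = 0.6, seed = 5))
  b <- make_bundle(bundle_spec(gate_cyt = 0.3, gate_peri = 0.6, seed = 5))
  expect_identical(coords(a), coords(b))

  gp <- bundle_gate_pairs(a)
  # cytoplasmic gate distance is strictly monotone in gate_cyt and
  # invariant to gate_peri (and vice versa)
  fr <- seq(0, 1, by = 0.25)
  d_cyt <- vapply(fr, function(g) {
    gate_distance(make_bundle(bundle_spec(gate_cyt = g, seed = 5)),
                  gp$cyt)
  }, numeric(1))
  expect_true(all(diff(d_cyt) > 0))
  d_peri <- vapply(fr, function(g) {
    gate_distance(make_bundle(bundle_spec(gate_peri = g, seed = 5)),
                  gp$peri)
  }, numeric(1))
  expect_true(all(diff(d_peri) > 0))

  base <- make_bundle(bundle_spec(gate_cyt = 0.2, gate_peri = 0.1,
                                  seed = 5))
  other <- make_bundle(bundle_spec(gate_cyt = 0.2, gate_peri = 0.9,
                                   seed = 5))
  expect_lt(abs(gate_distance(base, gp$cyt) -
                  gate_distance(other, gp$cyt)), 1e-6)
})

test_that("a fully closed bundle is occluded on both faces", {
  b <- make_bundle(bundle_spec(seed = 9))
  gp <- bundle_gate_pairs(b)
  thr <- state_thresholds()
  expect_lt(gate_distance(b, gp$cyt), thr$cyt_occluded_max)
  expect_lt(gate_distance(b, gp$peri), thr$peri_occluded_max)
})

test_that("transitions interpolate exactly and carry calibrated noise", {
  s <- make_bundle(bundle_spec(seed = 2))
  e <- make_bundle(bundle_spec(gate_cyt = 1, seed = 2))
  tr <- make_transition(s, e, 2, noise_sigma = 0, seed = 1)
  expect_equal(tr$frames[[1]], coords(s))
  expect_equal(tr$frames[[2]], coords(e))
  tr3 <- make_transition(s, e, 3, noise_sigma = 0, seed = 1)
  expect_equal(tr3$frames[[2]], (coords(s) + coords(e)) / 2)

  # noise SD calibration on a small system with many frames
  toy <- point_structure(matrix(rnorm(15), 5, 3))
  trn <- make_transition(toy, toy, 1000, noise_sigma = 0.3, seed = 4)
  dev <- unlist(lapply(trn$frames, function(f) f - coords(toy)))
  expect_lt(abs(sd(dev) - 0.3), 0.03)

  e2 <- e
  e2$atoms <- e2$atoms[-1, ]
  expect_error(make_transition(s, structure3d(e2$atoms), 5),
               "topology")
})

test_that("the soft ratchet drives the progress variable downhill", {
  set.seed(10)
  start <- point_structure(matrix(rnorm(30, sd = 3), 10, 3))
  target <- point_structure(coords(start) + matrix(rnorm(30, sd = 2),
                                                   10, 3))
  # target = start: phi ~ 0, run ends immediately but non-empty
  same <- soft_ratchet_sample(start, start, soft_ratchet_config(seed = 1),
                              progress_atoms = 1:10)
  expect_gte(n_frames(same), 1L)
  expect_lt(attr(same, "phi")[1], 0.5)

  # delta_phi -> infinity: acceptance ratio -> 1 (free diffusion)
  free <- soft_ratchet_sample(start, target,
                              soft_ratchet_config(delta_phi = 1e12,
                                                  step_sigma = 0.02,
                                                  max_steps = 200,
                                                  seed = 2),
                              progress_atoms = 1:10)
  expect_gte(n_frames(free), 0.95 * 200)

  # soft ratchet at the 1e-4 anchor value: overwhelmingly downhill
  wins <- 0L
  for (s in 1:100) {
    run <- soft_ratchet_sample(start, target,
                               soft_ratchet_config(delta_phi = 1e-4,
                                                   step_sigma = 0.05,
                                                   max_steps = 40,
                                                   seed = s),
                               progress_atoms = 1:10)
    phi <- attr(run, "phi")
    if (tail(phi, 1) < phi[1]) wins <- wins + 1L
  }
  expect_gte(wins, 99L)

  # nearly hard ratchet: phi sequence non-increasing
  hard <- soft_ratchet_sample(start, target,
                              soft_ratchet_config(delta_phi = 1e-12,
                                                  step_sigma = 0.05,
                                                  max_steps = 300,
                                                  seed = 3),
                              progress_atoms = 1:10)
  expect_true(all(diff(attr(hard, "phi")) <= 1e-12))
})

test_that("rotamer libraries are normalized, deterministic round-trippers", {
  one <- make_rotamer_library(1, seed = 3)
  expect_equal(one$weights, 1)
  for (n in c(2, 7, 30)) {
    lib <- make_rotamer_library(n, seed = n)
    expect_lt(abs(sum(lib$weights) - 1), 1e-12)
    lib2 <- make_rotamer_library(n, seed = n)
    expect_identical(lib$coords, lib2$coords)
    expect_identical(lib$weights, lib2$weights)
  }
  f <- withr::local_tempfile(fileext = ".txt")
  lib <- make_rotamer_library(5, seed = 8)
  write_rotamer_library(lib, f)
  lib2 <- read_rotamer_library(f)
  expect_equal(lib2$weights, lib$weights, tolerance = 1e-10)
  expect_equal(lib2$coords[[3]], lib$coords[[3]], tolerance = 1e-5)
  expect_identical(lib2$reporter_names, lib$reporter_names)
})

test_that("cavity waters follow Poisson statistics and avoid the protein", {
  box <- list(min = c(0, 0, 0), max = c(10, 10, 10))
  none <- fill_cavity_waters(NULL, box, 0, seed = 1)
  expect_equal(nrow(none[[1]]), 0L)

  counts <- vapply(1:40, function(s) {
    nrow(fill_cavity_waters(NULL, box, 0.0334, seed = s)[[1]])
  }, numeric(1))
  lambda <- 0.0334 * 1000
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 40))

  prot <- point_structure(matrix(5, 1, 3), vdw = 1.7)
  w <- fill_cavity_waters(prot, box, 0.05, seed = 2, n_frames = 5)
  for (f in w) {
    if (!nrow(f)) next
    d <- sqrt(rowSums(sweep(f, 2, c(5, 5, 5))^2))
    expect_gte(min(d), 2.6)
  }
})
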