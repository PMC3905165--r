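test_that("the Born equation gives the solvated-proton radius", {
  expect_equal(round(born_radius(1, -110.4, 80), 4), 1.4848)
  # forced by the formula: dG = -166 (1 - 1/80) gives exactly 1 A
  expect_equal(born_radius(1, -166 * (1 - 1 / 80), 80), 1)
  # q^2 scaling (4x the proton radius, ~5.939 A)
  expect_equal(born_radius(2, -110.4, 80), 4 * born_radius(1, -110.4, 80))
  expect_error(born_radius(1, 10, 80), "negative")
  expect_error(born_radius(0, -110.4, 80), "non-zero")
})

test_that("the Debye length at 100 mM, 298.15 K is ~9.6 A", {
  ld <- debye_length(0.1, 80, 298.15)
  expect_gt(ld, 9.4); expect_lt(ld, 9.9)
  expect_equal(debye_length(0, 80), Inf)
  # kappa^2 scales linearly with ionic strength
  expect_equal(debye_length(0.4, 80) * 2, debye_length(0.1, 80),
               tolerance = 1e-12)
})

test_that("dielectric maps follow the assignment precedence", {
  model <- dielectric_model()
  grid <- build_grid(c(-20, -20, -30), 2, c(21, 21, 31))
  # protein blob at the membrane midplane
  prot <- point_structure(matrix(c(10, 0, 0), 1, 3), vdw = 2)
  env <- build_dielectric_map(prot, model, grid)
  at <- function(p) {
    i <- round((p - grid$origin) / grid$spacing) + 1
    env$eps[i[1], i[2], i[3]]
  }
  expect_equal(at(c(0, 0, 0)), 2)     # core, far from protein
  expect_equal(at(c(0, 0, 20)), 20)   # head group
  expect_equal(at(c(0, 0, 28)), 80)   # bulk water
  expect_equal(at(c(10, 0, 0)), 10)   # protein beats membrane
  # solvent points reclaim interior voxels
  env2 <- build_dielectric_map(prot, model, grid,
                               solvent_points = matrix(c(10, 0, 0), 1, 3))
  i <- round((c(10, 0, 0) - grid$origin) / grid$spacing) + 1
  expect_equal(env2$eps[i[1], i[2], i[3]], 80)
  # screening only in water voxels
  expect_true(all(env$kappa2[env$eps != 80] == 0))
  expect_true(all(env$kappa2[env$eps == 80] > 0))
  # no membrane, no protein: uniform water
  env3 <- build_dielectric_map(NULL, model, grid, membrane = FALSE)
  expect_true(all(env3$eps == 80))
})

test_that("cavity points respect probe clearance and recover volumes", {
  bounds <- list(min = c(-6, -6, -6), max = c(6, 6, 6))
  full <- cavity_points(NULL, bounds, spacing = 1)
  expect_equal(nrow(full), 13^3)

  one <- point_structure(matrix(0, 1, 3), vdw = 2)
  pts <- cavity_points(one, bounds, spacing = 1, probe = 1.4)
  if (nrow(pts)) {
    d <- sqrt(rowSums(pts^2))
    expect_gte(min(d), 3.4)  # vdw + probe
  }

  # hollow shell (Fibonacci sphere): interior lattice points
  # recovered, count ~ analytic volume
  nsh <- 600
  i <- seq_len(nsh)
  th <- acos(1 - 2 * (i - 0.5) / nsh)
  ph <- pi * (1 + sqrt(5)) * i
  shell_xyz <- 8 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  shell <- point_structure(shell_xyz, vdw = 1.5, resid = seq_len(nsh))
  pts <- cavity_points(shell, list(min = c(-7, -7, -7),
                                   max = c(7, 7, 7)), spacing = 1)
  r <- sqrt(rowSums(pts^2))
  r_acc <- 8 - 1.5 - 1.4  # accessible interior radius
  # no accessible point inside the wall's exclusion band
  expect_true(all(r <= r_acc + 1e-9 | r >= 8))
  # the interior component matches the analytic sphere volume
  inner <- sum(r < 8)
  vol <- 4 / 3 * pi * r_acc^3
  expect_lt(abs(inner - vol) / vol, 0.1)
})

test_that("zero charge yields an identically zero potential", {
  grid <- build_grid(c(-5, -5, -5), 1, c(11, 11, 11))
  eps <- array(80, grid$dims); k2 <- array(0, grid$dims)
  phi <- solve_lpb(eps, k2, data.frame(x = 0, y = 0, z = 0, q = 0), grid)
  expect_true(all(phi == 0))
})

test_that("two charges in a uniform medium recover the Coulomb energy", {
  # solve for one charge, evaluate the potential at the other
  eps_u <- 4
  grid <- gatescape:::lpb_grid(c(0, 0, 0), 40, 65)
  eps <- array(eps_u, grid$dims); k2 <- array(0, grid$dims)
  q1 <- data.frame(x = -4, y = 0, z = 0, q = 1)
  phi <- solve_lpb(eps, k2, q1, grid, eps_boundary = eps_u)
  E_int <- 1 * gatescape:::interp_trilinear(phi, grid,
                                            matrix(c(4, 0, 0), 1, 3))
  E_coulomb <- 1389.35458 / (eps_u * 8)
  expect_lt(abs(E_int - E_coulomb) / E_coulomb, 0.03)
})

test_that("reaction-field energies superpose and scale as q^2", {
  sched <- focusing_schedule(list(c(40, 33), c(20, 33)))
  i1 <- born_ion(1, 1.5)
  i2 <- born_ion(2, 1.5)
  G1 <- born_solvation_energy(i1, 80, sched)
  G2 <- born_solvation_energy(i2, 80, sched)
  expect_lt(abs(G2 - 4 * G1) / abs(4 * G1), 0.02)
})

test_that("the focused Born energy approaches the analytic value", {
  ion <- born_ion(1, 1.4848)
  Ga <- born_energy_analytic(ion, 80)
  # very coarse two-level schedule (final h ~ 0.63 a): order-of-
  # magnitude agreement only
  G_coarse <- born_solvation_energy(ion, 80,
                                    focusing_schedule(list(c(60, 33),
                                                           c(30, 33))))
  expect_lt(abs(G_coarse - Ga) / abs(Ga), 0.15)
  # halving the spacing brings it closer
  G_fine <- born_solvation_energy(ion, 80,
                                  focusing_schedule(list(c(60, 33),
                                                         c(30, 65))))
  expect_lt(abs(G_fine - Ga), abs(G_coarse - Ga))
})

test_that("landscape points in bulk water sit at ~0 with protein charges", {
  # a small charged 'protein' in water, no membrane: a distant ion
  # feels only the screened interaction, W ~ 0
  prot <- point_structure(matrix(c(0, 0, 0), 1, 3), vdw = 2)
  prot$atoms$charge <- 1
  ion <- born_ion(1, 1.4848)
  sched <- focusing_schedule(list(c(60, 33), c(30, 33)))
  W <- born_landscape(prot, ion, dielectric_model(), sched,
                      points = matrix(c(0, 0, 12), 1, 3),
                      membrane = FALSE)
  expect_false(W$flagged[1])
  expect_lt(abs(W$W[1]), 2)
})
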