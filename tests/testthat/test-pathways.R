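test_that("the pore profiler recovers ring geometry", {
  ring <- ring_structure(n = 12, R = 5, vdw = 1.5)
  r <- pore_radius_at(ring, 0)
  expect_lt(abs(r$radius - 3.5), 0.1)
  expect_lt(sqrt(sum(r$center^2)), 0.1)

  # inner ring controls with two concentric rings
  outer <- ring_structure(n = 12, R = 9, vdw = 1.5)
  outer$atoms$resid <- outer$atoms$resid + 100
  both <- structure3d(rbind(ring$atoms, outer$atoms))
  expect_lt(abs(pore_radius_at(both, 0)$radius - 3.5), 0.1)

  # rotation invariance about the pore axis (axisymmetric fixture)
  rot <- set_coords(ring, coords(ring) %*%
                      t(rotation_matrix(c(0, 0, 1), 0.7)))
  expect_lt(abs(pore_radius_at(rot, 0)$radius -
                  pore_radius_at(ring, 0)$radius), 0.1)
})

test_that("degenerate slabs give sentinels and boundary-limited maxima", {
  ring <- ring_structure()
  expect_equal(pore_radius_at(ring, 50)$radius, Inf)  # empty slab
  lone <- point_structure(matrix(c(20, 0, 0), 1, 3), vdw = 1.7)
  r <- pore_radius_at(lone, 0, xy_start = c(0, 0), box_half = 5)
  expect_true(is.finite(r$radius))
  expect_true(all(abs(r$center) <= 5 + 1e-6))
})

test_that("profiles aggregate per-frame radii with mean and SD", {
  ring <- ring_structure(R = 5)
  one <- pore_profile(ring, z_grid = 0)
  expect_equal(one$sd_radius, 0)
  expect_equal(one$n, 1L)

  # frames alternating radii 3 and 5 -> mean 4, SD 1 (per z bin)
  f1 <- coords(ring_structure(R = 4.5))
  f2 <- coords(ring_structure(R = 6.5))
  ens <- ensemble3d(ring_structure(R = 4.5),
                    list(f1, f2, f1, f2))
  prof <- pore_profile(ens, z_grid = 0)
  expect_lt(abs(prof$mean_radius - 4), 0.1)
  expect_lt(abs(prof$sd_radius - 1), 0.12)
})

test_that("occluded bundles constrict below the water radius at both gates", {
  b <- make_bundle(bundle_spec(seed = 3))
  zg <- seq(-14, 14, by = 2)
  prof <- pore_profile(b, zg)
  expect_lt(min(prof$mean_radius[prof$z <= -10]), 1.4)
  expect_lt(min(prof$mean_radius[prof$z >= 10]), 1.4)
  # an open cytoplasmic face clears the sugar scale
  bo <- make_bundle(bundle_spec(gate_cyt = 1, seed = 3))
  profo <- pore_profile(bo, zg)
  expect_gt(min(profo$mean_radius[profo$z <= -10]), 3.5)
})

test_that("SPC bulk density converts to ~0.0324 waters per cubic Angstrom", {
  expect_equal(spc_bulk_number_density(),
               0.970 / 18.0154 * 6.02214076e23 / 1e24, tolerance = 1e-12)
  expect_lt(abs(spc_bulk_number_density() - 0.0324), 1e-3)
})

test_that("water density gridding is exact arithmetic with conservation", {
  # no waters -> all-zero field
  z <- water_density(matrix(numeric(0), 0, 3), origin = c(0, 0, 0),
                     spacing = 1, dims = c(5, 5, 5))
  expect_true(all(z$values == 0))

  # all waters in one voxel, 1 frame
  w <- matrix(rep(c(2, 2, 2), 4), 4, 3, byrow = TRUE)
  d <- water_density(w, origin = c(0, 0, 0), spacing = 1,
                     dims = c(5, 5, 5))
  expect_equal(d$values[3, 3, 3], 4 / (1 * spc_bulk_number_density()))
  expect_equal(sum(d$values > 0), 1L)

  # conservation: in-grid counts plus dropped equals total waters x frames
  set.seed(12)
  frames <- lapply(1:6, function(i) matrix(runif(60, -2, 7), 20, 3))
  class(frames) <- "water_frames"
  dd <- suppressMessages(
    water_density(frames, origin = c(0, 0, 0), spacing = 1,
                  dims = c(5, 5, 5)))
  expect_equal(sum(attr(dd, "counts")) + attr(dd, "dropped"), 120)

  # uniform waters at bulk density -> voxel mean ~1
  box <- list(min = c(0, 0, 0), max = c(12, 12, 12))
  wf <- fill_cavity_waters(NULL, box, spc_bulk_number_density(),
                           seed = 5, n_frames = 60)
  du <- water_density(wf, origin = c(1, 1, 1), spacing = 2,
                      dims = c(5, 5, 5))
  expect_lt(abs(mean(du$values) - 1), 0.05)
})

test_that("pathway connectivity matches a flood-fill oracle", {
  # solid column spanning both regions
  v <- array(0, c(3, 3, 10)); v[2, 2, ] <- 1
  fld <- scalar_field3d(c(0, 0, 0), 1, v, "relative_density")
  ra <- list(min = c(0, 0, 0), max = c(2, 2, 0))
  rb <- list(min = c(0, 0, 9), max = c(2, 2, 9))
  expect_true(pathway_connected(fld, 0.5, ra, rb)$connected)
  v2 <- v; v2[2, 2, 5] <- 0
  fld2 <- scalar_field3d(c(0, 0, 0), 1, v2, "relative_density")
  expect_false(pathway_connected(fld2, 0.5, ra, rb, 6)$connected)

  set.seed(33)
  for (rep in 1:12) {
    vals <- array(runif(8 * 8 * 8), c(8, 8, 8))
    f <- scalar_field3d(c(0, 0, 0), 1, vals, "relative_density")
    rA <- list(min = c(0, 0, 0), max = c(7, 7, 0))
    rB <- list(min = c(0, 0, 7), max = c(7, 7, 7))
    for (conn in c(6, 26)) {
      got <- pathway_connected(f, 0.5, rA, rB, conn)$connected
      want <- floodfill_connected(vals >= 0.5,
                                  list(1:8, 1:8, 1L),
                                  list(1:8, 1:8, 8L), conn)
      expect_identical(got, want)
    }
  }
})

test_that("raising the threshold never creates connectivity", {
  set.seed(44)
  vals <- array(runif(512), c(8, 8, 8))
  f <- scalar_field3d(c(0, 0, 0), 1, vals, "relative_density")
  rA <- list(min = c(0, 0, 0), max = c(7, 7, 0))
  rB <- list(min = c(0, 0, 7), max = c(7, 7, 7))
  verdicts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    pathway_connected(f, th, rA, rB)$connected, logical(1))
  expect_true(all(diff(as.integer(verdicts)) <= 0))
})

test_that("OpenDX fields round-trip", {
  set.seed(3)
  fld <- scalar_field3d(c(-2, 0, 1), 0.5,
                        array(rnorm(4 * 3 * 5), c(4, 3, 5)),
                        "relative_density")
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(fld, f)
  fld2 <- read_dx(f, semantics = "relative_density")
  expect_equal(fld2$origin, fld$origin)
  expect_equal(fld2$spacing, fld$spacing)
  expect_equal(fld2$values, fld$values, tolerance = 1e-6)
})
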