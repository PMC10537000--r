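test_that("ion boxes are reproducible, excluded from the slab, and valid", {
  fb <- flat_bottom_restraint(r = 0.3, k = 10000)
  sys <- make_ion_box(c(3, 3, 8.3), n_pairs = 108, restraint = fb, seed = 17)
  expect_equal(nrow(sys$particles), 216L)
  d <- abs(min_image(sys$particles$z, 8.3))
  expect_true(all(d >= 0.3))
  sys2 <- make_ion_box(c(3, 3, 8.3), n_pairs = 108, restraint = fb, seed = 17)
  expect_identical(sys$particles, sys2$particles)
  expect_false(identical(
    sys$particles,
    make_ion_box(c(3, 3, 8.3), 108, restraint = fb, seed = 18)$particles))
  # empty system
  empty <- make_ion_box(c(3, 3, 8.3), n_pairs = 0, restraint = fb, seed = 1)
  expect_equal(nrow(empty$particles), 0L)
  # infeasible placement volume
  expect_error(make_ion_box(c(3, 3, 0.5), 4, restraint = fb, seed = 1),
               "too small")
  # structures pass placement validation and round-trip through GRO
  s <- ion_box_structure(sys)
  v <- validate_ion_sides(s, c("NA" = "lower", "CL" = "lower")[0], c(3, 5), fb)
  expect_true(v$pass)   # no species mapped: vacuously valid placement
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro(s, f)
  s2 <- read_gro(f)
  expect_equal(s2$z, round(s$z, 3), tolerance = 1e-9)
})

test_that("side-restricted ion boxes occupy the requested half-box", {
  fb <- flat_bottom_restraint(r = 0.2, k = 1000)
  lo <- make_ion_box(c(3, 3, 8.2), 20, restraint = fb, seed = 3, side = "lower")
  expect_true(all(lo$particles$z > 0.2 & lo$particles$z < 4.1))
  hi <- make_ion_box(c(3, 3, 8.2), 20, restraint = fb, seed = 3, side = "upper")
  expect_true(all(hi$particles$z > 4.1 & hi$particles$z < 8.0))
})

test_that("bilayer fixtures are deterministic and carry ground truth", {
  spec <- bilayer_fixture_spec(lipids_per_leaflet = 6, n_waters = 20, seed = 5)
  t1 <- make_bilayer_trajectory(spec, n_frames = 3)
  t2 <- make_bilayer_trajectory(spec, n_frames = 3)
  expect_identical(t1$coords, t2$coords)
  gt <- ground_truth(t1)
  expect_named(gt$scd, c("carbon", "scd"))
  expect_equal(nrow(gt$pn_pairs), 12L)
  expect_true(all(c("o", "h1", "h2") %in% names(gt$waters)))
  # generator refuses unphysical order-parameter targets
  expect_error(bilayer_fixture_spec(scd_targets = c(0.2, 1.4)), "-0.5")
  expect_error(bilayer_fixture_spec(scd_targets = c(-0.7)), "-0.5")
})

test_that("water geometry is rigid and dipoles follow the field exactly", {
  spec <- bilayer_fixture_spec(lipids_per_leaflet = 4, n_waters = 50,
                               dipole_field = function(z) rep(0.25, length(z)),
                               seed = 6)
  traj <- make_bilayer_trajectory(spec, n_frames = 2)
  gt <- ground_truth(traj)
  pos <- frame_coords(traj, 1)
  mi <- function(a, b) {
    sapply(1:3, function(ax) min_image(pos[a, ax] - pos[b, ax],
                                       spec$box[ax]))
  }
  oh1 <- mi(gt$waters$h1, gt$waters$o)
  oh2 <- mi(gt$waters$h2, gt$waters$o)
  expect_equal(sqrt(rowSums(oh1^2)), rep(0.09572, 50), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(oh2^2)), rep(0.09572, 50), tolerance = 1e-9)
  ang <- acos(rowSums(oh1 * oh2) / (0.09572^2)) * 180 / pi
  expect_equal(ang, rep(104.52, 50), tolerance = 1e-6)
  mid <- (oh1 + oh2) / 2
  cosd <- mid[, 3] / sqrt(rowSums(mid^2))
  expect_equal(cosd, rep(0.25, 50), tolerance = 1e-9)
})

test_that("doubling a structure doubles atoms and the box height", {
  fb <- flat_bottom_restraint(r = 0.3, k = 1000)
  sys <- make_ion_box(c(3, 3, 8.3), 10, restraint = fb, seed = 2)
  s <- ion_box_structure(sys)
  d <- make_double_bilayer(s)
  expect_equal(nrow(d), 2L * nrow(s))
  expect_equal(attr(d, "box")[3], 2 * attr(s, "box")[3])
  expect_equal(wrap_box(d$z[nrow(s) + 1], 16.6), wrap_box(16.6 - s$z[1], 16.6),
               tolerance = 1e-9)
})
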