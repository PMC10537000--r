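static_traj <- function(zs, box = c(3, 3, 8), xy = 1.5, atoms = NULL,
                        frames = 1) {
  n <- length(zs)
  coords <- array(NA_real_, c(frames, n, 3))
  for (f in seq_len(frames)) {
    coords[f, , 1] <- xy
    coords[f, , 2] <- xy
    coords[f, , 3] <- zs
  }
  fb_trajectory(coords, times = seq_len(frames), box = box, atoms = atoms)
}

test_that("uniformly spread atoms give a flat profile at N / V", {
  Lz <- 8
  n <- 160
  traj <- static_traj((seq_len(n) - 0.5) * Lz / n)
  prof <- density_profile(traj, seq_len(n))
  expect_equal(prof$value, rep(n / (3 * 3 * Lz), length(prof$z)),
               tolerance = 1e-12)
  expect_equal(profile_integral(prof), n, tolerance = 1e-9)
})

test_that("two delta layers give two peaks whose integral is the atom count", {
  traj <- static_traj(c(rep(2.05, 36), rep(6.05, 36)))
  prof <- density_profile(traj, 1:72)
  peaks <- prof$z[prof$value > 0]
  expect_equal(sort(peaks), c(2.05, 6.05))
  expect_equal(profile_integral(prof), 72, tolerance = 1e-9)
})

test_that("profiles conserve the mean selected-atom count (random content)", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    nf <- sample(2:4, 1)
    coords <- array(runif(nf * n * 3, 0, 5), c(nf, n, 3))
    traj <- fb_trajectory(coords, times = seq_len(nf), box = c(5, 5, 5))
    prof <- density_profile(traj, seq_len(n), bin_width = 0.17)
    expect_equal(profile_integral(prof), n, tolerance = 1e-6)
    # centered variant conserves as well
    prof2 <- density_profile(traj, seq_len(n), bin_width = 0.17, center = 1:3)
    expect_equal(profile_integral(prof2), n, tolerance = 1e-6)
  }
})

test_that("zero-frame or empty selections are rejected", {
  traj <- static_traj(c(1, 2))
  expect_error(density_profile(traj, integer(0)), "empty")
  expect_error(density_profile(traj, 5), "out of range")
})

water_traj <- function(dipole, zo = 4, n = 10) {
  # n identical waters with a prescribed unit dipole direction
  dipole <- dipole / sqrt(sum(dipole^2))
  perp <- if (abs(dipole[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- perp - dipole * sum(perp * dipole)
  perp <- perp / sqrt(sum(perp^2))
  half <- 104.52 / 2 * pi / 180
  o <- cbind(runif(n, 1, 2), runif(n, 1, 2), rep(zo, n))
  h1 <- o + 0.09572 * rep(1, n) %o% (cos(half) * dipole + sin(half) * perp)
  h2 <- o + 0.09572 * rep(1, n) %o% (cos(half) * dipole - sin(half) * perp)
  coords <- array(NA_real_, c(1, 3 * n, 3))
  idx <- seq(1, 3 * n, by = 3)
  coords[1, idx, ] <- o
  coords[1, idx + 1, ] <- h1
  coords[1, idx + 2, ] <- h2
  atoms <- tibble::tibble(
    name = rep(c("OW", "HW1", "HW2"), n),
    resname = "SOL",
    resid = rep(seq_len(n), each = 3)
  )
  fb_trajectory(coords, times = 0, box = c(3, 3, 8), atoms = atoms)
}

test_that("water dipoles along +z give +1 times the oxygen density", {
  set.seed(1)
  traj <- water_traj(c(0, 0, 1))
  prof <- water_orientation_profile(traj)
  dens <- density_profile(traj, atom_select(traj, name == "OW"))
  expect_equal(prof$value, dens$value, tolerance = 1e-9)
  expect_equal(prof$mean_cos[prof$o_density > 0], 1, tolerance = 1e-9)
})

test_that("in-plane dipoles give exactly zero and opposite dipoles negate", {
  set.seed(2)
  flat <- water_orientation_profile(water_traj(c(1, 1, 0)))
  expect_equal(max(abs(flat$value)), 0, tolerance = 1e-12)
  down <- water_orientation_profile(water_traj(c(0, 0, -1)))
  expect_equal(min(down$mean_cos), -1, tolerance = 1e-9)
  expect_true(all(abs(down$value) <= down$o_density + 1e-12))
})

test_that("incomplete waters are reported by residue", {
  traj <- water_traj(c(0, 0, 1), n = 3)
  at <- traj$atoms
  at$name[5] <- "XX"  # break second water's first hydrogen
  broken <- fb_trajectory(traj$coords, traj$times, traj$box, at)
  expect_error(water_orientation_profile(broken), "2")
})

test_that("profile comparison metrics behave", {
  traj <- static_traj((seq_len(80) - 0.5) / 10)
  a <- density_profile(traj, 1:80)
  expect_equal(glance(compare_profiles(a, a))$rms, 0)
  b <- a
  b$value <- b$value + 0.25
  cmp <- compare_profiles(a, b)
  expect_equal(cmp$max_abs, 0.25, tolerance = 1e-12)
  expect_equal(cmp$rms, 0.25, tolerance = 1e-12)
  expect_false(cmp$resampled)
  # different grids trigger (flagged) interpolation
  c2 <- density_profile(traj, 1:80, bin_width = 0.13)
  cmp2 <- compare_profiles(a, c2)
  expect_true(cmp2$resampled)
  # disjoint supports are an error
  d <- a
  d$z <- d$z + 100
  expect_error(compare_profiles(a, d), "disjoint")
})

test_that("independently sampled profiles differ at the sampling-noise level", {
  # two independent uniform samples of the same generator: the rms difference
  # should match the binomial per-bin noise sqrt(2 * npb) / (bin volume * F)
  set.seed(33)
  n <- 4000
  nf <- 1
  bw <- 0.5
  box <- c(3, 3, 8)
  mk <- function() {
    coords <- array(c(runif(n, 0, 3), runif(n, 0, 3), runif(n, 0, 8)),
                    c(1, n, 3))
    density_profile(fb_trajectory(coords, 0, box), seq_len(n), bin_width = bw)
  }
  cmp <- compare_profiles(mk(), mk())
  npb <- n * bw / 8                      # expected atoms per bin
  pred <- sqrt(2 * npb) / (bw * 9)       # sd of per-bin density difference
  expect_gt(cmp$rms, pred * 0.5)
  expect_lt(cmp$rms, pred * 2)
})
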