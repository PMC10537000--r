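test_that("inverted potential matches the closed quadratic form", {
  fb <- flat_bottom_restraint(z_ref = 0, r = 0.3, k = 10000)
  expect_equal(fb_potential(fb, 0), 450)
  expect_equal(fb_potential(fb, 0.15), 112.5)
  expect_equal(fb_potential(fb, 0.3), 0)
  expect_equal(fb_potential(fb, 5), 0)
  expect_equal(fb_potential(fb, -0.15), fb_potential(fb, 0.15))  # symmetry
  # off-centre reference plane
  fb2 <- flat_bottom_restraint(z_ref = 1.2, r = 0.3, k = 10000)
  expect_equal(fb_potential(fb2, 1.2 + 0.15), 112.5)
  expect_error(fb_potential(fb, NaN), "non-finite")
  expect_error(fb_potential(fb, Inf), "non-finite")
})

test_that("regular (non-inverted) form is the complement", {
  fb <- flat_bottom_restraint(r = 0.3, k = 10000, inverted = FALSE)
  expect_equal(fb_potential(fb, 0), 0)
  expect_equal(fb_potential(fb, 0.45), 112.5)
  expect_equal(fb_force(fb, 0.45), -1500)   # pulls back towards the slab
  expect_equal(fb_force(fb, -0.45), 1500)
})

test_that("force is the analytic gradient with the tie-break at the plane", {
  fb <- flat_bottom_restraint(r = 0.3, k = 10000)
  expect_equal(fb_force(fb, 0.15), 1500)
  expect_equal(fb_force(fb, -0.15), -1500)
  expect_equal(fb_force(fb, 0.3), 0)
  expect_equal(fb_force(fb, 0), 0)
  # negative centred finite difference of V away from the kinks
  zs <- setdiff(seq(-0.6, 0.6, by = 0.01), c(-0.3, 0, 0.3))
  h <- 1e-7
  fd <- -(fb_potential(fb, zs + h) - fb_potential(fb, zs - h)) / (2 * h)
  expect_equal(fb_force(fb, zs), fd, tolerance = 1e-6)
})

test_that("potential is non-negative and zero exactly outside the slab", {
  fb <- flat_bottom_restraint(r = 0.25, k = 3000)
  z <- seq(-4, 4, by = 0.001)
  v <- fb_potential(fb, z)
  expect_true(all(v >= 0))
  expect_identical(v[abs(z) >= 0.25], rep(0, sum(abs(z) >= 0.25)))
  expect_true(all(v[abs(z) < 0.25] > 0))
})

test_that("barrier height is k r^2 / 2", {
  expect_equal(fb_barrier(flat_bottom_restraint(r = 0.3, k = 10000)), 450)
  expect_equal(fb_barrier(flat_bottom_restraint(r = 0.3, k = 100)), 4.5)
  expect_error(fb_barrier(flat_bottom_restraint(r = 0.3, k = 1, inverted = FALSE)),
               "inverted")
})

test_that("excluded width: limits, monotonicity in k, quadrature value", {
  th <- thermal_state(310)
  r <- 0.3
  expect_equal(fb_excluded_width(flat_bottom_restraint(r = r, k = 1e9), th),
               2 * r, tolerance = 1e-3)
  expect_equal(fb_excluded_width(flat_bottom_restraint(r = r, k = 0), th), 0)
  # frozen quadrature value for the calibrated restraint:
  # 2r - sqrt(2 pi kT / k) erf(r sqrt(k / 2 kT)) at 310 K
  w <- fb_excluded_width(flat_bottom_restraint(r = 0.3, k = 10000), th)
  expect_equal(w, 0.559757, tolerance = 1e-5)
  ks <- 10^seq(0, 8, length.out = 17)
  ws <- vapply(ks, function(k) {
    fb_excluded_width(flat_bottom_restraint(r = r, k = k), th)
  }, numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_true(all(ws > 0 & ws < 2 * r))
  # hotter solvent penetrates deeper: width shrinks with T
  w400 <- fb_excluded_width(flat_bottom_restraint(r = 0.3, k = 10000),
                            thermal_state(400))
  expect_lt(w400, w)
})

test_that("extra-water count matches the dimensional-analysis oracle", {
  sol <- solvent_spec(A_xy = 9, rho_w = 997)
  expect_equal(extra_water_count(sol, 0.3), oracle_extra_water(9, 0.3, 997),
               tolerance = 1e-12)
  expect_equal(round(extra_water_count(sol, 0.3)), 180)
  expect_equal(extra_water_count(sol, 0), 0)
  # linearity in the cross-section
  expect_equal(extra_water_count(solvent_spec(A_xy = 18), 0.3),
               2 * extra_water_count(solvent_spec(A_xy = 9), 0.3))
  set.seed(1)
  for (i in 1:100) {
    A <- runif(1, 1, 100)
    r <- runif(1, 0, 1)
    rho <- runif(1, 900, 1100)
    expect_equal(extra_water_count(solvent_spec(A, rho), r),
                 oracle_extra_water(A, r, rho), tolerance = 1e-9)
  }
  expect_error(extra_water_count(sol, -0.1), "non-negative")
})

test_that("constructors validate their inputs", {
  expect_error(flat_bottom_restraint(r = 0), "positive")
  expect_error(flat_bottom_restraint(r = 0.3, k = -1), "non-negative")
  expect_error(thermal_state(T = -1))
  expect_error(solvent_spec(A_xy = 0), "positive")
  expect_error(solvent_spec(A_xy = 9, rho_w = -2), "positive")
  expect_equal(thermal_state(310)$kT, 8.314462618e-3 * 310)
})
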