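# Shared helpers and independent oracles for the test suite.

# single-particle trajectory from a wrapped z series (x = y = 0)
z_series_traj <- function(zs, Lz, Lxy = 3) {
  coords <- array(0, c(length(zs), 1L, 3L))
  coords[, 1, 3] <- zs
  fb_trajectory(coords, times = seq_along(zs), box = c(Lxy, Lxy, Lz))
}

# Brute-force crossing oracle: unwrap the path step by step and walk every
# boundary segment, honouring the rule that a point exactly on a plane
# belongs with the next non-zero displacement.
oracle_crossings <- function(zs, L, plane = 0) {
  d <- diff(zs)
  d <- d - L * round(d / L)
  u <- cumsum(c(zs[1] - plane, d))
  n <- 0L
  pending <- 0L   # side the particle came from while sitting on a plane
  for (j in seq_along(d)) {
    a <- u[j]
    b <- u[j + 1]
    if (b == a) next
    if (a == floor(a / L) * L) {
      if (pending == -1L && b > a) n <- n + 1L
      if (pending == +1L && b < a) n <- n + 1L
      pending <- 0L
    }
    lo <- min(a, b)
    hi <- max(a, b)
    m <- seq(ceiling(lo / L), floor(hi / L))
    m <- m[m * L > lo & m * L < hi]
    n <- n + length(m)
    if (b == floor(b / L) * L) pending <- if (b > a) -1L else +1L
  }
  n
}

# Eq.-style dimensional-analysis oracle for the extra-water count, written in
# SI units throughout (independent of the package's nm bookkeeping).
oracle_extra_water <- function(A_xy_nm2, r_nm, rho_kg_m3,
                               M_kg_mol = 0.018016, N_A = 6.02214076e23) {
  slab_m3 <- (2 * r_nm * 1e-9) * (A_xy_nm2 * 1e-18)
  slab_m3 * rho_kg_m3 / M_kg_mol * N_A
}

# Boltzmann CDF for one particle in a box [0, L) with the inverted restraint
# centred on the box edge (plane at z = 0 == z = L)
boltzmann_cdf <- function(restraint, thermal, L) {
  beta <- 1 / thermal$kT
  dens <- function(z) exp(-beta * fb_potential(restraint, pmin(z, L - z)))
  Z <- stats::integrate(dens, 0, L)$value
  Vectorize(function(q) stats::integrate(dens, 0, q)$value / Z)
}

expect_within_3se <- function(value, truth, se, floor_tol = 1e-8) {
  expect_lt(abs(value - truth), max(3 * se, floor_tol))
}
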