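#' Molar Boltzmann constant in kJ mol^-1 K^-1
#'
#' @format Length-one numeric.
#' @export
kB_KJ_MOL_K <- 8.314462618e-3

#' Avogadro constant in mol^-1
#'
#' @format Length-one numeric.
#' @export
N_AVOGADRO <- 6.02214076e23

#' Flat-bottom restraint specification
#'
#' Defines a flat-bottom restraint acting on the z coordinate, centred on a
#' reference plane `z_ref`. In the *inverted* form (the default, and the form
#' used to confine ions to one side of a membrane) the potential is zero
#' everywhere except inside a slab of width `2 r` centred on the plane, where
#' it grows quadratically towards a maximum of `k r^2 / 2` at the plane
#' itself. The regular (non-inverted) form is the complement: zero inside the
#' slab, quadratic outside.
#'
#' @param z_ref Position of the restraint plane (nm). For confining solutes
#'   to one side of a periodically repeated bilayer this is 0, the box edge.
#' @param r Half-width of the restrained slab (nm); must be positive.
#' @param k Force constant (kJ mol^-1 nm^-2); must be non-negative.
#' @param inverted Logical; `TRUE` (default) selects the inverted form.
#' @return An object of class `fb_restraint`.
#' @examples
#' fb <- flat_bottom_restraint(z_ref = 0, r = 0.3, k = 10000)
#' fb_barrier(fb)  # 450 kJ/mol
#' @export
flat_bottom_restraint <- function(z_ref = 0, r = 0.3, k = 10000, inverted = TRUE) {
  stopifnot(is.numeric(z_ref), length(z_ref) == 1L, is.finite(z_ref))
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be a single positive number (nm)", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("`k` must be a single non-negative number (kJ/mol/nm^2)", call. = FALSE)
  }
  structure(
    list(z_ref = as.numeric(z_ref), r = as.numeric(r), k = as.numeric(k),
         inverted = isTRUE(inverted)),
    class = "fb_restraint"
  )
}

#' @export
print.fb_restraint <- function(x, ...) {
  cat(sprintf(
    "<fb_restraint> %s form: z_ref = %g nm, r = %g nm, k = %g kJ/mol/nm^2 (barrier %g kJ/mol)\n",
    if (x$inverted) "inverted" else "regular", x$z_ref, x$r, x$k,
    if (x$inverted) fb_barrier(x) else NA_real_
  ))
  invisible(x)
}

check_z <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    stop("non-finite z coordinate: corrupt input coordinates", call. = FALSE)
  }
  as.numeric(z)
}

#' Flat-bottom potential energy
#'
#' Evaluates the restraint potential at coordinates `z` (vectorised). For the
#' inverted form this is `k (|z - z_ref| - r)^2 / 2` where `|z - z_ref| < r`
#' and exactly zero elsewhere; the regular form is the complement. The
#' potential is continuous everywhere and symmetric about `z_ref`.
#'
#' @param restraint An [flat_bottom_restraint()] object.
#' @param z Coordinate(s) in nm.
#' @return Energies in kJ/mol, same length as `z`.
#' @export
fb_potential <- function(restraint, z) {
  stopifnot(inherits(restraint, "fb_restraint"))
  z <- check_z(z)
  d <- abs(z - restraint$z_ref)
  if (restraint$inverted) {
    ifelse(d < restraint$r, 0.5 * restraint$k * (d - restraint$r)^2, 0)
  } else {
    ifelse(d > restraint$r, 0.5 * restraint$k * (d - restraint$r)^2, 0)
  }
}

#' Axial force exerted by a flat-bottom restraint
#'
#' Negative gradient of [fb_potential()] with respect to `z`. Inside the
#' inverted slab the force has magnitude `k (r - |z - z_ref|)` and points away
#' from the plane; it is exactly zero at the slab boundary and beyond. At
#' `z == z_ref` the gradient is discontinuous and the force is defined as 0
#' (symmetric tie-break on a measure-zero set).
#'
#' @inheritParams fb_potential
#' @return Forces in kJ mol^-1 nm^-1, same length as `z`.
#' @export
fb_force <- function(restraint, z) {
  stopifnot(inherits(restraint, "fb_restraint"))
  z <- check_z(z)
  s <- z - restraint$z_ref
  d <- abs(s)
  if (restraint$inverted) {
    ifelse(d < restraint$r & d > 0, restraint$k * (restraint$r - d) * sign(s), 0)
  } else {
    ifelse(d > restraint$r, -restraint$k * (d - restraint$r) * sign(s), 0)
  }
}

#' Barrier height of an inverted flat-bottom restraint
#'
#' The maximum of the potential, attained at the restraint plane:
#' `k r^2 / 2`.
#'
#' @inheritParams fb_potential
#' @return Energy in kJ/mol.
#' @export
fb_barrier <- function(restraint) {
  stopifnot(inherits(restraint, "fb_restraint"))
  if (!restraint$inverted) {
    stop("barrier height is defined for the inverted form only", call. = FALSE)
  }
  0.5 * restraint$k * restraint$r^2
}

#' Thermal state (temperature and thermal energy)
#'
#' @param T Temperature in K; must be positive.
#' @param kB Molar Boltzmann constant (kJ mol^-1 K^-1).
#' @return An object of class `fb_thermal` with fields `T`, `kB` and the
#'   precomputed thermal energy `kT` (kJ/mol).
#' @export
thermal_state <- function(T = 310, kB = kB_KJ_MOL_K) {
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T), T > 0)
  structure(list(T = T, kB = kB, kT = kB * T), class = "fb_thermal")
}

#' Boltzmann-weighted excluded width of an inverted restraint
#'
#' The effective width of solvent from which restrained particles are
#' depleted at equilibrium,
#' \deqn{w = \int (1 - e^{-V(z)/k_B T})\, dz}
#' taken over the restrained slab. A hard wall excludes exactly `2 r`; the
#' quadratic barrier excludes slightly less. Closed form:
#' `w = 2 r - sqrt(2 pi kT / k) * erf(r sqrt(k / (2 kT)))`, evaluated here by
#' adaptive quadrature of the defining integral.
#'
#' @inheritParams fb_potential
#' @param thermal A [thermal_state()].
#' @return Width in nm, in `[0, 2 r)`; increases with `k`, tends to `2 r` as
#'   `k` grows and to 0 as `k` vanishes.
#' @examples
#' fb_excluded_width(flat_bottom_restraint(r = 0.3, k = 10000), thermal_state(310))
#' @export
fb_excluded_width <- function(restraint, thermal = thermal_state()) {
  stopifnot(inherits(restraint, "fb_restraint"), inherits(thermal, "fb_thermal"))
  if (!restraint$inverted) {
    stop("excluded width is defined for the inverted form only", call. = FALSE)
  }
  if (restraint$k == 0) return(0)
  beta <- 1 / thermal$kT
  f <- function(z) 1 - exp(-beta * fb_potential(restraint, z))
  stats::integrate(f,
                   lower = restraint$z_ref - restraint$r,
                   upper = restraint$z_ref + restraint$r,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Solvent specification for the extra-water estimate
#'
#' @param A_xy Box cross-sectional area perpendicular to the restraint axis
#'   (nm^2).
#' @param rho_w Water mass density (kg m^-3). Default 997 (ambient liquid
#'   water).
#' @param M_w Molar mass of water (kg mol^-1). Default 0.018016
#'   (18.016 g/mol).
#' @param N_A Avogadro constant (mol^-1).
#' @return An object of class `fb_solvent`.
#' @export
solvent_spec <- function(A_xy, rho_w = 997, M_w = 0.018016, N_A = N_AVOGADRO) {
  vals <- c(A_xy = A_xy, rho_w = rho_w, M_w = M_w, N_A = N_A)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all solvent_spec fields must be strictly positive and finite", call. = FALSE)
  }
  structure(as.list(vals), class = "fb_solvent")
}

#' Extra water molecules needed to compensate a hard-wall exclusion
#'
#' Number of water molecules occupying a slab of thickness `2 r` over the box
#' cross-section: `N_w = 2 r A_xy rho_w / M_w * N_A` (with lengths converted
#' from nm). This is the step-function estimate of how much extra solvent to
#' add when an inverted flat-bottom restraint depletes a slab of width `2 r`;
#' because the quadratic barrier is softer than a step, the Boltzmann
#' excluded width ([fb_excluded_width()]) is marginally smaller.
#'
#' @param solvent A [solvent_spec()].
#' @param r Restraint half-width in nm; must be non-negative.
#' @return Real (not rounded) molecule count; round for placement.
#' @examples
#' extra_water_count(solvent_spec(A_xy = 9), r = 0.3)  # ~180
#' @export
extra_water_count <- function(solvent, r) {
  stopifnot(inherits(solvent, "fb_solvent"))
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0) {
    stop("`r` must be a single non-negative number (nm)", call. = FALSE)
  }
  vol_m3 <- 2 * r * solvent$A_xy * 1e-27       # nm^3 -> m^3
  vol_m3 * solvent$rho_w / solvent$M_w * solvent$N_A
}
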