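#' Reference diffusion coefficients for aqueous ions
#'
#' Experimental bulk self-diffusion coefficients at ambient conditions, in
#' nm^2/ps: Na+ 1.33e-3, Cl- 2.03e-3.
#'
#' @format Named numeric vector.
#' @export
ION_DIFFUSION <- c("NA" = 1.33e-3, "CL" = 2.03e-3)

#' Parameters for the overdamped-Langevin (Brownian) propagator
#'
#' The calibration analog replaces explicit-solvent MD with non-interacting
#' Brownian particles in an implicit solvent: each particle is advanced by
#' `dz = (F / gamma) dt + sqrt(2 D dt) xi` with friction `gamma = kB T / D`
#' and `xi` a standard normal deviate, independently on all three axes (the
#' restraint force acts on z only).
#'
#' @param duration Total simulated time in ns.
#' @param thermal A [thermal_state()]; default 310 K.
#' @param diffusion Named vector mapping species to diffusion coefficients
#'   (nm^2/ps). Default [ION_DIFFUSION].
#' @param dt Timestep in ps, or `NULL` to choose automatically: 0.01 ps for
#'   stiff restraints (`k >= 1e4`), 0.1 ps otherwise, halved until the
#'   stability guard `sqrt(2 D dt) < r / 5` holds for every species.
#' @param record_interval Interval between recorded frames in ps; chosen so
#'   the free-diffusion RMS displacement per interval stays well under half
#'   the box, keeping minimal-image crossing detection unambiguous.
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @return An object of class `fb_brownian_params`.
#' @export
brownian_params <- function(duration = 100, thermal = thermal_state(),
                            diffusion = ION_DIFFUSION, dt = NULL,
                            record_interval = 1, seed = 1L) {
  stopifnot(duration > 0, record_interval > 0, is.numeric(diffusion),
            all(diffusion > 0), !is.null(names(diffusion)))
  if (!is.null(dt)) stopifnot(dt > 0)
  structure(
    list(duration = duration, thermal = thermal, diffusion = diffusion,
         dt = dt, record_interval = record_interval, seed = as.integer(seed)),
    class = "fb_brownian_params"
  )
}

#' Default Brownian timestep for a restraint
#'
#' 0.01 ps for stiff restraints (`k >= 1e4` kJ/mol/nm^2), 0.1 ps otherwise,
#' halved until the per-step free-diffusion RMS displacement satisfies
#' `sqrt(2 D dt) < r / 5` for every species.
#'
#' @param restraint An [flat_bottom_restraint()].
#' @param diffusion Named vector of diffusion coefficients (nm^2/ps).
#' @return Timestep in ps.
#' @export
default_timestep <- function(restraint, diffusion = ION_DIFFUSION) {
  dt <- if (restraint$k >= 1e4) 0.01 else 0.1
  Dmax <- max(diffusion)
  while (sqrt(2 * Dmax * dt) >= restraint$r / 5) dt <- dt / 2
  dt
}

check_stability <- function(restraint, diffusion, dt) {
  rms <- sqrt(2 * diffusion * dt)
  bad <- rms >= restraint$r / 5
  if (any(bad)) {
    stop(sprintf(
      paste0("timestep %g ps violates the stability guard sqrt(2 D dt) < r/5 ",
             "for species %s (RMS step %s nm vs bound %g nm); reduce dt"),
      dt, paste(names(diffusion)[bad], collapse = ", "),
      paste(signif(rms[bad], 3), collapse = ", "), restraint$r / 5
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate an ion box under a flat-bottom restraint
#'
#' Runs the overdamped-Langevin analog of the salt-solution calibration:
#' non-interacting particles diffuse in a periodic box while the inverted
#' flat-bottom restraint at the box edge repels them from the reference
#' plane. Positions are wrapped into the box each step and recorded at
#' `record_interval`.
#'
#' @param system An `fb_ion_box` from [make_ion_box()].
#' @param params An [fb_brownian_params][brownian_params()].
#' @return An [fb_trajectory()] whose `atoms` tibble carries the species and
#'   side labels and which records the active restraint.
#' @export
simulate_ion_box <- function(system, params) {
  stopifnot(inherits(system, "fb_ion_box"), inherits(params, "fb_brownian_params"))
  restraint <- system$restraint
  sp <- system$particles$species
  missing_sp <- setdiff(unique(sp), names(params$diffusion))
  if (length(missing_sp)) {
    stop("no diffusion coefficient for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  D <- unname(params$diffusion[sp])
  dt <- params$dt %||% default_timestep(restraint, params$diffusion[unique(sp)])
  check_stability(restraint, params$diffusion[unique(sp)], dt)

  rec_steps <- max(1L, round(params$record_interval / dt))
  nsteps <- round(params$duration * 1000 / dt)
  nsteps <- rec_steps * max(1L, round(nsteps / rec_steps))

  pos0 <- as.matrix(system$particles[, c("x", "y", "z")])
  out <- bd_simulate_cpp(pos0, system$box, restraint$z_ref,
                         restraint$r, restraint$k, restraint$inverted,
                         D, params$thermal$kT, dt, nsteps, rec_steps,
                         as.double(params$seed))
  fb_trajectory(
    coords = out$coords, times = out$times, box = system$box,
    atoms = tibble::tibble(species = sp, side = system$particles$side),
    restraint = restraint
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
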