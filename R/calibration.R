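#' Number-density profile of a species along z (box coordinates)
#'
#' Convenience wrapper over [density_profile()] for calibration runs: bins
#' the named species along z in box coordinates, with the restraint zone of
#' the trajectory carried along so downstream bulk averaging can refuse
#' perturbed bins.
#'
#' @param traj An [fb_trajectory()] whose atoms carry a `species` column.
#' @param species Species label(s) to profile, or `NULL` for all atoms.
#' @param bin_width Bin width (nm), default 0.1.
#' @return An `fb_profile` (number density, nm^-3) over `[0, Lz)`.
#' @export
density_along_z <- function(traj, species = NULL, bin_width = 0.1) {
  stopifnot(inherits(traj, "fb_trajectory"))
  sel <- if (is.null(species)) {
    seq_len(n_atoms(traj))
  } else {
    atom_select(traj, .data$species %in% !!species)
  }
  density_profile(traj, sel, bin_width = bin_width, center = NULL,
                  label = paste(species %||% "all", collapse = "+"))
}

restrained_zone <- function(profile) {
  restraint <- attr(profile, "restraint")
  if (is.null(restraint) || restraint$k == 0) return(NULL)
  Lz <- attr(profile, "Lz")
  plane <- wrap_box(restraint$z_ref, Lz)
  r <- restraint$r
  # intervals of the wrapped box within r of the plane
  ints <- list(c(plane - r, plane + r))
  out <- list()
  for (iv in ints) {
    lo <- iv[1]; hi <- iv[2]
    if (lo < 0) out <- c(out, list(c(lo + Lz, Lz), c(0, hi)))
    else if (hi > Lz) out <- c(out, list(c(lo, Lz), c(0, hi - Lz)))
    else out <- c(out, list(c(lo, hi)))
  }
  out
}

#' Bulk density over an unperturbed region of a profile
#'
#' Mean and standard deviation of the bin densities over the given
#' z-interval. The interval must lie within the profile support and must not
#' overlap the restrained zone (perturbed bins would bias the bulk
#' estimate).
#'
#' @param profile An `fb_profile` from [density_along_z()] /
#'   [density_profile()].
#' @param region Length-2 numeric `c(lo, hi)` in the profile's z coordinate.
#'   Default: the central 4 nm of the profile.
#' @return Tibble with `mean` (nm^-3), `sd` (nm^-3), `n_bins`.
#' @export
bulk_density <- function(profile, region = NULL) {
  stopifnot(inherits(profile, "fb_profile"))
  zmin <- min(profile$z) - attr(profile, "bin_width") / 2
  zmax <- max(profile$z) + attr(profile, "bin_width") / 2
  if (is.null(region)) {
    mid <- (zmin + zmax) / 2
    region <- c(mid - 2, mid + 2)
  }
  stopifnot(length(region) == 2L, region[1] < region[2])
  if (region[1] < zmin - 1e-9 || region[2] > zmax + 1e-9) {
    stop("region outside profile support", call. = FALSE)
  }
  for (iv in restrained_zone(profile)) {
    if (region[1] < iv[2] - 1e-9 && region[2] > iv[1] + 1e-9) {
      stop(sprintf(
        "region [%g, %g] overlaps the restrained zone [%g, %g]; perturbed bins would bias the bulk estimate",
        region[1], region[2], iv[1], iv[2]), call. = FALSE)
    }
  }
  keep <- profile$z >= region[1] & profile$z <= region[2]
  if (!any(keep)) stop("empty bulk region", call. = FALSE)
  vals <- profile$value[keep]
  tibble::tibble(mean = mean(vals), sd = stats::sd(vals), n_bins = sum(keep))
}

#' Reference bulk density from an unrestrained ion box
#'
#' Runs the Brownian analog in the unextended box with the restraint force
#' switched off and returns the bulk ion density, the reference against
#' which the extra-water scan is matched.
#'
#' @param restraint Restraint whose geometry (half-width) defines the
#'   perturbed zone margins used for the bulk region; its force constant is
#'   ignored (set to zero for the run).
#' @param params An [fb_brownian_params][brownian_params()].
#' @param base_box Unextended box (nm), default `c(3, 3, 8)`.
#' @param n_pairs,species Ion content, as in [make_ion_box()].
#' @param species_profiled Species whose density is profiled; default the
#'   first species (the cation).
#' @param bin_width,bulk_margin See [optimize_extra_water()].
#' @param duration_factor Reference run length as a multiple of
#'   `params$duration`.
#' @return Tibble from [bulk_density()].
#' @export
reference_bulk_density <- function(restraint, params = brownian_params(duration = 25),
                                   base_box = c(3, 3, 8), n_pairs = 108,
                                   species = c("NA", "CL"),
                                   species_profiled = species[1],
                                   bin_width = 0.1, bulk_margin = 0.1,
                                   duration_factor = 10) {
  free <- flat_bottom_restraint(z_ref = restraint$z_ref, r = restraint$r, k = 0)
  sys <- make_ion_box(box = base_box, n_pairs = n_pairs, species = species,
                      restraint = free, seed = params$seed)
  # the unrestrained run takes a 10x larger timestep, so a duration_factor-long
  # reference costs about as much as one restrained scan point; the reference
  # error is a common shift of the whole scan, so it is worth suppressing
  ref_params <- params
  ref_params$duration <- params$duration * duration_factor
  traj <- simulate_ion_box(sys, ref_params)
  prof <- density_along_z(traj, species_profiled, bin_width)
  region <- c(restraint$r + bulk_margin, base_box[3] - restraint$r - bulk_margin)
  bulk_density(prof, region)
}

#' Optimal extra-water layer thickness by density matching
#'
#' Scans a grid of extra solvent-layer thicknesses: for each thickness `t`
#' the box's long dimension is `base + t`, the restrained Brownian analog is
#' run, and the bulk ion density in the unperturbed region is compared with
#' the unrestrained reference. The optimum is the grid thickness whose bulk
#' density comes closest to the reference (ties towards the smaller
#' thickness). For a hard wall the optimum is exactly `2 r`; for the
#' quadratic barrier it is the slightly smaller Boltzmann excluded width
#' ([fb_excluded_width()]).
#'
#' @param restraint The inverted flat-bottom restraint under calibration.
#' @param thickness_grid Extra thicknesses to scan (nm), e.g.
#'   `seq(0, 0.8, 0.1)`.
#' @param params An [fb_brownian_params][brownian_params()]; the default
#'   duration for scan runs is 25 ns per grid point.
#' @param reference_density Reference bulk density (nm^-3) from an
#'   unrestrained run of the unextended box, or `NULL` to compute it with
#'   [reference_bulk_density()].
#' @param base_box Unextended box (nm), default `c(3, 3, 8)`.
#' @param n_pairs,species Ion content, as in [make_ion_box()].
#' @param species_profiled Species profiled for the density match.
#' @param bin_width Profile bin width (nm).
#' @param bulk_margin Margin (nm) beyond the restraint half-width excluded
#'   from bulk averaging on each side. The bulk region spans every bin
#'   farther than `bulk_margin + r` from the restraint plane: all
#'   unperturbed bins share the bulk expectation, so the widest window is
#'   the lowest-variance estimator.
#' @return A list of class `fb_water_scan`: `optimum` (nm), `scan` (tibble:
#'   `thickness`, `bulk`, `sd`, `abs_diff`), `reference` (nm^-3).
#' @export
optimize_extra_water <- function(restraint, thickness_grid,
                                 params = brownian_params(duration = 25),
                                 reference_density = NULL,
                                 base_box = c(3, 3, 8), n_pairs = 108,
                                 species = c("NA", "CL"),
                                 species_profiled = species[1],
                                 bin_width = 0.1, bulk_margin = 0.1) {
  if (length(thickness_grid) == 0L) {
    stop("thickness grid is empty", call. = FALSE)
  }
  thickness_grid <- sort(as.numeric(thickness_grid))
  if (is.null(reference_density)) {
    reference_density <- reference_bulk_density(
      restraint, params, base_box, n_pairs, species, species_profiled,
      bin_width, bulk_margin)$mean
  }
  rows <- purrr::map_dfr(thickness_grid, function(t) {
    box <- c(base_box[1:2], base_box[3] + t)
    sys <- make_ion_box(box = box, n_pairs = n_pairs, species = species,
                        restraint = restraint, seed = params$seed)
    traj <- simulate_ion_box(sys, params)
    prof <- density_along_z(traj, species_profiled, bin_width)
    region <- c(restraint$r + bulk_margin, box[3] - restraint$r - bulk_margin)
    b <- bulk_density(prof, region)
    tibble::tibble(thickness = t, bulk = b$mean, sd = b$sd)
  })
  rows$abs_diff <- abs(rows$bulk - reference_density)
  structure(
    list(optimum = rows$thickness[which.min(rows$abs_diff)],
         scan = rows, reference = reference_density,
         restraint = restraint),
    class = "fb_water_scan"
  )
}

#' @export
print.fb_water_scan <- function(x, ...) {
  cat(sprintf(
    "<fb_water_scan> optimum extra-water thickness %.2g nm (reference density %.4g nm^-3)\n",
    x$optimum, x$reference))
  print(x$scan)
  invisible(x)
}

#' @export
tidy.fb_water_scan <- function(x, ...) x$scan

#' @export
glance.fb_water_scan <- function(x, ...) {
  tibble::tibble(optimum = x$optimum, reference = x$reference,
                 n_thickness = nrow(x$scan))
}

#' @export
autoplot.fb_water_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$thickness, y = .data$bulk)) +
    ggplot2::geom_hline(yintercept = object$reference, colour = "red") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$bulk - .data$sd,
                                          ymax = .data$bulk + .data$sd)) +
    ggplot2::labs(x = "extra water thickness (nm)",
                  y = "bulk density (nm^-3)")
}
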