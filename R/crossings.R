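#' Count restraint-plane crossings in a trajectory
#'
#' Detects every event in which the minimal-image path between consecutive
#' recorded frames carries a particle through the plane `plane_z` (or any of
#' its periodic images along z). A frame landing exactly on the plane is held
#' pending and counted with the sign of the next non-zero displacement.
#' Reliable detection requires consecutive-frame displacements to be small
#' compared with `Lz / 2`; a warning is issued otherwise.
#'
#' @param traj An [fb_trajectory()].
#' @param plane_z Plane position along z (nm). Default 0, the box edge.
#' @return An object of class `fb_crossing_report`: a list with `events`
#'   (tibble: `time` ps, `particle`, `species`, `direction` +1/-1), `counts`
#'   (tibble: per-species crossing count) and `total_time` (ps).
#' @export
count_plane_crossings <- function(traj, plane_z = 0) {
  stopifnot(inherits(traj, "fb_trajectory"))
  if (n_frames(traj) < 2L) {
    stop("need at least two frames to detect crossings", call. = FALSE)
  }
  Lz <- traj$box[1, 3]
  if (stats::sd(traj$box[, 3]) > 0) {
    stop("crossing detection requires a constant box z-dimension", call. = FALSE)
  }
  z <- traj$coords[, , 3]
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  dz <- abs(min_image(z[-1, , drop = FALSE] - z[-nrow(z), , drop = FALSE], Lz))
  if (max(dz) > Lz / 4) {
    warning("inter-frame displacements exceed Lz/4; crossings may be missed",
            call. = FALSE)
  }
  ev <- count_crossings_cpp(z, Lz, plane_z)
  species <- if (!is.null(traj$atoms) && "species" %in% names(traj$atoms)) {
    traj$atoms$species
  } else {
    rep("all", n_atoms(traj))
  }
  events <- tibble::tibble(
    time = traj$times[ev$frame],
    particle = ev$particle,
    species = species[ev$particle],
    direction = ev$direction
  )
  events <- dplyr::arrange(events, .data$time, .data$particle)
  counts <- dplyr::count(
    tibble::tibble(species = factor(species[ev$particle], levels = unique(species))),
    .data$species, .drop = FALSE, name = "crossings"
  )
  counts$species <- as.character(counts$species)
  structure(
    list(events = events, counts = tibble::as_tibble(counts),
         total_time = diff(range(traj$times)), plane_z = plane_z),
    class = "fb_crossing_report"
  )
}

#' @export
print.fb_crossing_report <- function(x, ...) {
  cat(sprintf("<fb_crossing_report> %d crossings in %g ns at plane z = %g nm\n",
              nrow(x$events), x$total_time / 1000, x$plane_z))
  print(x$counts)
  invisible(x)
}

#' Total number of crossings in a report
#' @param report An `fb_crossing_report`.
#' @return Integer.
#' @export
n_crossings <- function(report) {
  stopifnot(inherits(report, "fb_crossing_report"))
  nrow(report$events)
}

#' @export
tidy.fb_crossing_report <- function(x, ...) x$events

#' @export
glance.fb_crossing_report <- function(x, ...) {
  tibble::tibble(
    crossings = nrow(x$events),
    total_time_ns = x$total_time / 1000,
    rate_per_ns = nrow(x$events) / (x$total_time / 1000),
    plane_z = x$plane_z
  )
}

#' Scan crossing counts over a grid of restraint parameters
#'
#' Mirrors the salt-solution calibration: for every `(r, k)` pair an ion box
#' is built with the long box dimension extended by `r` (keeping the
#' unperturbed region at its nominal size), the Brownian analog is run, and
#' plane crossings at the box edge are counted.
#'
#' @param r_values Restraint half-widths to scan (nm).
#' @param k_values Force constants to scan (kJ/mol/nm^2).
#' @param params An [fb_brownian_params][brownian_params()]; the same seed is
#'   used for every cell, making the scan deterministic.
#' @param base_box Unextended box dimensions (nm); default `c(3, 3, 8)`.
#' @param n_pairs Ion pairs per box; default 108.
#' @param species Two species labels for the pair; default Na+/Cl-.
#' @return Tibble with one row per `(r, k)` cell: crossing count, barrier
#'   height (kJ/mol and kT units), and the crossing rate per ns. The reports
#'   themselves are in the list-column `report`.
#' @export
scan_rk_grid <- function(r_values, k_values, params = brownian_params(),
                         base_box = c(3, 3, 8), n_pairs = 108,
                         species = c("NA", "CL")) {
  if (length(r_values) == 0L || length(k_values) == 0L) {
    return(tibble::tibble(r = numeric(), k = numeric(), crossings = integer(),
                          barrier = numeric(), barrier_kT = numeric(),
                          rate_per_ns = numeric(), report = list()))
  }
  grid <- tidyr::expand_grid(r = as.numeric(r_values), k = as.numeric(k_values))
  res <- purrr::pmap(grid, function(r, k) {
    restraint <- flat_bottom_restraint(z_ref = 0, r = r, k = k)
    box <- c(base_box[1:2], base_box[3] + r)
    sys <- make_ion_box(box = box, n_pairs = n_pairs, species = species,
                        restraint = restraint, seed = params$seed)
    traj <- simulate_ion_box(sys, params)
    count_plane_crossings(traj, plane_z = 0)
  })
  dplyr::mutate(
    grid,
    crossings = purrr::map_int(res, n_crossings),
    barrier = 0.5 * .data$k * .data$r^2,
    barrier_kT = .data$barrier / params$thermal$kT,
    rate_per_ns = .data$crossings / (params$duration),
    report = res
  )
}
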