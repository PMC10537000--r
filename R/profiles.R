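#' @importFrom rlang .data
NULL

# Minimal-image center of mass along z, anchored on the first atom of the
# selection so the result is deterministic and periodic-boundary safe.
com_z_frame <- function(z, Lz, mass = NULL) {
  ref <- z[1]
  off <- min_image(z - ref, Lz)
  m <- if (is.null(mass)) rep(1, length(z)) else mass
  wrap_box(ref + sum(off * m) / sum(m), Lz)
}

profile_grid <- function(zmin, zmax, bin_width) {
  nbins <- max(1L, round((zmax - zmin) / bin_width))
  edges <- seq(zmin, zmax, length.out = nbins + 1L)
  list(edges = edges, centers = (edges[-1] + edges[-(nbins + 1L)]) / 2,
       width = (zmax - zmin) / nbins, nbins = nbins)
}

new_fb_profile <- function(z, value, kind, label, bin_width, frames, area,
                           extra = list()) {
  out <- tibble::tibble(z = z, value = value)
  out <- tibble::new_tibble(out, class = "fb_profile")
  attr(out, "kind") <- kind
  attr(out, "label") <- label
  attr(out, "bin_width") <- bin_width
  attr(out, "frames") <- frames
  attr(out, "area") <- area
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

# core binned profile: values (per frame x atom) at coordinates (same shape),
# averaged over frames and converted to a per-volume quantity
bin_profile <- function(zvals, weights, grid, area, frames) {
  idx <- findInterval(zvals, grid$edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  keep <- idx >= 1L & idx <= grid$nbins
  sums <- rep(0, grid$nbins)
  if (any(keep)) {
    agg <- tapply(weights[keep], idx[keep], sum)
    sums[as.integer(names(agg))] <- as.numeric(agg)
  }
  sums / (frames * area * grid$width)
}

#' Number-density profile along the box normal
#'
#' Histograms the z coordinates of a selection frame by frame, optionally
#' after recentering each frame on the center of mass of a reference
#' selection (typically the membrane), and converts counts to a number
#' density (nm^-3) averaged over frames. The profile integrates to the mean
#' selected-atom count per frame.
#'
#' @param x An [fb_trajectory()], or an `fb_bilayer_split` from
#'   [split_double_bilayer()] (in which case the per-membrane profiles are
#'   computed in each membrane's own centered frame and averaged bin-wise).
#' @param selection Atom indices (or logical mask) to profile.
#' @param bin_width Bin width in nm; default 0.1.
#' @param center Atom indices of a centering selection, or `NULL` to bin in
#'   box coordinates `[0, Lz)`. When centering, coordinates are reported
#'   relative to the per-frame reference COM, spanning `(-Lz/2, Lz/2]`.
#' @param label Selection label stored with the profile.
#' @param ... Passed between methods.
#' @return An `fb_profile` tibble with columns `z` (bin centers, nm) and
#'   `value` (number density, nm^-3).
#' @export
density_profile <- function(x, selection, bin_width = 0.1, ...) {
  UseMethod("density_profile")
}

#' @rdname density_profile
#' @export
density_profile.fb_trajectory <- function(x, selection, bin_width = 0.1,
                                          center = NULL, label = "selection",
                                          ...) {
  traj <- x
  nf <- n_frames(traj)
  if (nf == 0L) stop("trajectory has zero frames", call. = FALSE)
  sel <- resolve_selection(traj, selection)
  stopifnot(bin_width > 0)
  Lz <- max(traj$box[, 3])
  area <- mean(traj$box[, 1] * traj$box[, 2])
  mass <- atom_masses(traj)

  if (is.null(center)) {
    grid <- profile_grid(0, Lz, bin_width)
    zvals <- wrap_box(traj$coords[, sel, 3], Lz)
  } else {
    cen <- resolve_selection(traj, center, "centering selection")
    grid <- profile_grid(-Lz / 2, Lz / 2, bin_width)
    zvals <- matrix(NA_real_, nf, length(sel))
    for (f in seq_len(nf)) {
      Lzf <- traj$box[f, 3]
      com <- com_z_frame(traj$coords[f, cen, 3], Lzf, mass[cen])
      zvals[f, ] <- min_image(traj$coords[f, sel, 3] - com, Lzf)
    }
  }
  dens <- bin_profile(as.numeric(zvals), rep(1, length(zvals)), grid, area, nf)
  new_fb_profile(grid$centers, dens, "number_density", label, grid$width, nf,
                 area,
                 extra = list(restraint = traj$restraint,
                              centered = !is.null(center), Lz = Lz))
}

atom_masses <- function(traj) {
  if (!is.null(traj$atoms) && "mass" %in% names(traj$atoms)) {
    traj$atoms$mass
  } else {
    NULL
  }
}

#' Identify the three atoms of each water molecule
#'
#' Groups atoms of the given residue name into (O, H, H) triplets by residue
#' id, erroring with the offending residue ids if any water is incomplete.
#'
#' @param traj An [fb_trajectory()] whose atoms carry `resname`, `resid` and
#'   `name` columns.
#' @param resname Water residue name; default `"SOL"`.
#' @return Tibble with columns `o`, `h1`, `h2` (atom indices).
#' @export
water_indices <- function(traj, resname = "SOL") {
  stopifnot(inherits(traj, "fb_trajectory"), !is.null(traj$atoms))
  at <- dplyr::mutate(traj$atoms, .idx = dplyr::row_number())
  w <- dplyr::filter(at, .data$resname == !!resname)
  if (nrow(w) == 0L) stop("no atoms with resname ", resname, call. = FALSE)
  grouped <- dplyr::summarise(
    dplyr::group_by(w, .data$resid),
    o = list(.data$.idx[startsWith(.data$name, "O")]),
    h = list(.data$.idx[startsWith(.data$name, "H")]),
    .groups = "drop"
  )
  bad <- grouped$resid[lengths(grouped$o) != 1L | lengths(grouped$h) != 2L]
  if (length(bad)) {
    stop("water residues without exactly one O and two H atoms: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    o = purrr::map_int(grouped$o, 1),
    h1 = purrr::map_int(grouped$h, 1),
    h2 = purrr::map_int(grouped$h, 2)
  )
}

water_dipole_cos <- function(traj, waters, f) {
  pos <- frame_coords(traj, f)
  box <- traj$box[f, ]
  vm <- matrix(0, nrow(waters), 3)
  for (a in 1:3) {
    mid <- (min_image(pos[waters$h1, a] - pos[waters$o, a], box[a]) +
            min_image(pos[waters$h2, a] - pos[waters$o, a], box[a])) / 2
    vm[, a] <- mid
  }
  vm[, 3] / sqrt(rowSums(vm^2))
}

#' Water dipole orientation profile
#'
#' For each bin along z, the mean cosine of the angle between the water
#' dipole (from the oxygen through the H-H midpoint) and the +z axis,
#' multiplied by the local number density of water oxygens. Positive values
#' mean dipoles pointing towards +z.
#'
#' @inheritParams density_profile
#' @param waters Tibble of water atom triplets from [water_indices()], or a
#'   residue name string to resolve automatically.
#' @return An `fb_profile` tibble (kind `"orientation"`) with columns `z`,
#'   `value` (cos x density, nm^-3) plus `o_density` and `mean_cos`.
#' @export
water_orientation_profile <- function(x, waters = "SOL", bin_width = 0.1, ...) {
  UseMethod("water_orientation_profile")
}

#' @rdname water_orientation_profile
#' @export
water_orientation_profile.fb_trajectory <- function(x, waters = "SOL",
                                                    bin_width = 0.1,
                                                    center = NULL, ...) {
  traj <- x
  if (is.character(waters)) waters <- water_indices(traj, waters)
  stopifnot(all(c("o", "h1", "h2") %in% names(waters)), nrow(waters) > 0)
  nf <- n_frames(traj)
  Lz <- max(traj$box[, 3])
  area <- mean(traj$box[, 1] * traj$box[, 2])
  mass <- atom_masses(traj)

  grid <- if (is.null(center)) profile_grid(0, Lz, bin_width) else
    profile_grid(-Lz / 2, Lz / 2, bin_width)

  zs <- matrix(NA_real_, nf, nrow(waters))
  cs <- matrix(NA_real_, nf, nrow(waters))
  cen <- if (is.null(center)) NULL else
    resolve_selection(traj, center, "centering selection")
  for (f in seq_len(nf)) {
    Lzf <- traj$box[f, 3]
    zo <- traj$coords[f, waters$o, 3]
    if (!is.null(cen)) {
      com <- com_z_frame(traj$coords[f, cen, 3], Lzf, mass[cen])
      zo <- min_image(zo - com, Lzf)
    } else {
      zo <- wrap_box(zo, Lzf)
    }
    zs[f, ] <- zo
    cs[f, ] <- water_dipole_cos(traj, waters, f)
  }
  dens <- bin_profile(as.numeric(zs), rep(1, length(zs)), grid, area, nf)
  wsum <- bin_profile(as.numeric(zs), as.numeric(cs), grid, area, nf)
  out <- new_fb_profile(grid$centers, wsum, "orientation", "water dipole",
                        grid$width, nf, area,
                        extra = list(restraint = traj$restraint,
                                     centered = !is.null(center), Lz = Lz))
  out$o_density <- dens
  out$mean_cos <- ifelse(dens > 0, wsum / dens, 0)
  out
}

#' Integrate a profile
#'
#' For a number-density profile this recovers the mean selected-atom count
#' per frame (bin volume x density summed over bins).
#'
#' @param profile An `fb_profile`.
#' @return Numeric scalar.
#' @export
profile_integral <- function(profile) {
  stopifnot(inherits(profile, "fb_profile"))
  sum(profile$value) * attr(profile, "bin_width") * attr(profile, "area")
}

#' Compare two profiles on a common grid
#'
#' Computes the per-bin difference `b - a`, its root-mean-square and its
#' maximum absolute value. If the bin grids differ, `b` is linearly
#' interpolated onto the grid of `a` over the overlapping support (flagged in
#' the result); disjoint supports are an error.
#'
#' @param a,b `fb_profile` objects of the same kind.
#' @return A list of class `fb_profile_comparison`: `rms`, `max_abs`,
#'   `resampled`, and `delta` (tibble `z`, `a`, `b`, `delta`).
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "fb_profile"), inherits(b, "fb_profile"))
  if (!identical(attr(a, "kind"), attr(b, "kind"))) {
    warning("comparing profiles of different kinds", call. = FALSE)
  }
  resampled <- !(length(a$z) == length(b$z) && all(a$z == b$z))
  if (resampled) {
    lo <- max(min(a$z), min(b$z))
    hi <- min(max(a$z), max(b$z))
    if (lo >= hi) stop("profiles have disjoint supports", call. = FALSE)
    keep <- a$z >= lo & a$z <= hi
    if (!any(keep)) stop("profiles have disjoint supports", call. = FALSE)
    za <- a$z[keep]
    va <- a$value[keep]
    vb <- stats::approx(b$z, b$value, xout = za)$y
  } else {
    za <- a$z
    va <- a$value
    vb <- b$value
  }
  delta <- vb - va
  structure(
    list(rms = sqrt(mean(delta^2)), max_abs = max(abs(delta)),
         resampled = resampled,
         delta = tibble::tibble(z = za, a = va, b = vb, delta = delta)),
    class = "fb_profile_comparison"
  )
}

#' @export
print.fb_profile_comparison <- function(x, ...) {
  cat(sprintf("<fb_profile_comparison> rms = %.4g, max |delta| = %.4g%s\n",
              x$rms, x$max_abs, if (x$resampled) " (resampled)" else ""))
  invisible(x)
}

#' @export
glance.fb_profile_comparison <- function(x, ...) {
  tibble::tibble(rms = x$rms, max_abs = x$max_abs, resampled = x$resampled)
}

#' @export
autoplot.fb_profile <- function(object, ...) {
  ylab <- switch(attr(object, "kind"),
                 number_density = "number density (nm^-3)",
                 orientation = "<cos theta> x density (nm^-3)",
                 "value")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = ylab, title = attr(object, "label"))
}
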