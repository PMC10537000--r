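#' Split a double-bilayer trajectory into two centered sub-analyses
#'
#' A double-bilayer system encloses two solvent compartments between two
#' stacked membranes. For profile analyses, each observable is computed in
#' each membrane's own centered frame — every non-membrane atom being
#' assigned to the compartment of the nearer membrane (minimal-image z
#' distance to the membrane COMs) — and the two profiles are then averaged
#' bin-wise. Because the two membranes face in opposite directions along z,
#' the second membrane's profile is flipped (z reversed; sign also reversed
#' for orientation profiles) before averaging, so equivalent leaflets line
#' up.
#'
#' @param traj An [fb_trajectory()] containing both membranes.
#' @param selection_1,selection_2 Disjoint atom selections defining the two
#'   membranes.
#' @param flip_second Flip the second membrane's profiles before averaging
#'   (default `TRUE`, matching the stacked head-to-head construction).
#' @return An object of class `fb_bilayer_split`; pass it to
#'   [density_profile()] or [water_orientation_profile()].
#' @export
split_double_bilayer <- function(traj, selection_1, selection_2,
                                 flip_second = TRUE) {
  stopifnot(inherits(traj, "fb_trajectory"))
  s1 <- resolve_selection(traj, selection_1, "membrane selection 1")
  s2 <- resolve_selection(traj, selection_2, "membrane selection 2")
  if (length(intersect(s1, s2)) > 0L) {
    stop("membrane selections overlap", call. = FALSE)
  }
  structure(
    list(traj = traj, sel = list(s1, s2), flip_second = isTRUE(flip_second)),
    class = "fb_bilayer_split"
  )
}

# per-frame membrane COMs and atom->compartment assignment
split_assignment <- function(split, f) {
  traj <- split$traj
  Lz <- traj$box[f, 3]
  mass <- atom_masses(traj)
  coms <- vapply(split$sel, function(s) {
    com_z_frame(traj$coords[f, s, 3], Lz, mass[s])
  }, numeric(1))
  z <- traj$coords[f, , 3]
  d1 <- abs(min_image(z - coms[1], Lz))
  d2 <- abs(min_image(z - coms[2], Lz))
  list(coms = coms, compartment = ifelse(d1 <= d2, 1L, 2L))
}

split_profile <- function(split, selection, bin_width, kind, waters = NULL) {
  traj <- split$traj
  nf <- n_frames(traj)
  if (nf == 0L) stop("trajectory has zero frames", call. = FALSE)
  Lz <- max(traj$box[, 3])
  area <- mean(traj$box[, 1] * traj$box[, 2])
  # each membrane's compartment spans at most half the doubled box
  grid <- profile_grid(-Lz / 4, Lz / 4, bin_width)

  values <- vector("list", 2L)
  for (m in 1:2) {
    zlist <- vector("list", nf)
    wlist <- vector("list", nf)
    for (f in seq_len(nf)) {
      Lzf <- traj$box[f, 3]
      asn <- split_assignment(split, f)
      # fold by the compartment period Lz/2: each membrane's compartment spans
      # half the doubled box, so relative coordinates live in (-Lz/4, Lz/4]
      # exactly as they would in the corresponding single-bilayer box
      if (is.null(waters)) {
        sel <- selection[asn$compartment[selection] == m]
        zlist[[f]] <- min_image(traj$coords[f, sel, 3] - asn$coms[m], Lzf / 2)
        wlist[[f]] <- rep(1, length(sel))
      } else {
        keep <- asn$compartment[waters$o] == m
        w <- waters[keep, , drop = FALSE]
        zlist[[f]] <- min_image(traj$coords[f, w$o, 3] - asn$coms[m], Lzf / 2)
        wlist[[f]] <- water_dipole_cos(traj, w, f)
      }
    }
    values[[m]] <- bin_profile(unlist(zlist), unlist(wlist), grid, area, nf)
  }
  if (split$flip_second) {
    values[[2]] <- rev(values[[2]])
    if (kind == "orientation") values[[2]] <- -values[[2]]
  }
  avg <- (values[[1]] + values[[2]]) / 2
  new_fb_profile(grid$centers, avg, kind, "double-bilayer average",
                 grid$width, nf, area,
                 extra = list(restraint = traj$restraint, centered = TRUE,
                              Lz = Lz / 2,
                              per_membrane = values))
}

#' @rdname density_profile
#' @export
density_profile.fb_bilayer_split <- function(x, selection, bin_width = 0.1,
                                             ...) {
  sel <- resolve_selection(x$traj, selection)
  split_profile(x, sel, bin_width, "number_density")
}

#' @rdname water_orientation_profile
#' @export
water_orientation_profile.fb_bilayer_split <- function(x, waters = "SOL",
                                                       bin_width = 0.1, ...) {
  if (is.character(waters)) waters <- water_indices(x$traj, waters)
  split_profile(x, NULL, bin_width, "orientation", waters = waters)
}
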