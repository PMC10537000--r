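#' Block-averaged standard error of a time series
#'
#' Splits a (stationary) series into `n_blocks` equal contiguous blocks and
#' returns the standard error of the block means. With correlated samples
#' this is a far less optimistic error estimate than the naive standard
#' error, provided blocks are longer than the correlation time.
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks; default 5.
#' @return Standard error (same units as `x`).
#' @export
block_se <- function(x, n_blocks = 5) {
  stopifnot(n_blocks >= 2)
  n <- length(x)
  if (n < n_blocks) return(NA_real_)
  idx <- floor(seq_along(x) * n_blocks / (n + 1e-9)) + 1L
  idx[idx > n_blocks] <- n_blocks
  means <- tapply(x, idx, mean)
  stats::sd(means) / sqrt(length(means))
}

# per-frame leaflet sign relative to the membrane COM: +1 upper, -1 lower
# (atoms exactly at the COM plane go to the lower leaflet)
leaflet_sign <- function(zrel) ifelse(zrel > 0, 1L, -1L)

#' Area per lipid
#'
#' Time-averaged lateral box area divided by the number of non-cholesterol
#' lipids in one leaflet, reported in Angstrom^2 with a block-averaged
#' standard error. Cholesterol is excluded from the divisor by convention;
#' pass per-leaflet counts that already omit it.
#'
#' @param traj An [fb_trajectory()].
#' @param lipids_per_leaflet Either a single count (symmetric membrane) or a
#'   named vector `c(lower = , upper = )` of non-cholesterol lipid counts.
#' @param n_blocks Blocks for the error estimate.
#' @return Tibble with columns `leaflet`, `apl` (A^2), `se` (A^2).
#' @export
area_per_lipid <- function(traj, lipids_per_leaflet, n_blocks = 5) {
  stopifnot(inherits(traj, "fb_trajectory"))
  counts <- lipids_per_leaflet
  if (length(counts) == 1L && is.null(names(counts))) {
    counts <- c(lower = counts, upper = counts)
  }
  if (any(counts <= 0)) {
    stop("non-cholesterol lipid count per leaflet must be positive", call. = FALSE)
  }
  area_A2 <- traj$box[, 1] * traj$box[, 2] * 100  # nm^2 -> A^2
  purrr::map_dfr(names(counts), function(lf) {
    tibble::tibble(
      leaflet = lf,
      apl = mean(area_A2) / counts[[lf]],
      se = block_se(area_A2 / counts[[lf]], n_blocks)
    )
  })
}

#' Membrane thickness from phosphorus positions
#'
#' D_P-P: the distance along z between the mean phosphorus position of the
#' upper and lower leaflets, averaged over frames. Leaflets are assigned per
#' frame by the sign of the minimal-image z relative to the phosphorus COM.
#'
#' @param traj An [fb_trajectory()].
#' @param p_selection Indices of the phosphorus atoms.
#' @param n_blocks Blocks for the error estimate.
#' @return Tibble with `d_pp` (nm), `se` (nm), `n_frames`.
#' @export
membrane_thickness <- function(traj, p_selection, n_blocks = 5) {
  stopifnot(inherits(traj, "fb_trajectory"))
  sel <- resolve_selection(traj, p_selection, "phosphorus selection")
  mass <- atom_masses(traj)
  nf <- n_frames(traj)
  per_frame <- vapply(seq_len(nf), function(f) {
    Lz <- traj$box[f, 3]
    z <- traj$coords[f, sel, 3]
    com <- com_z_frame(z, Lz, mass[sel])
    zrel <- min_image(z - com, Lz)
    s <- leaflet_sign(zrel)
    if (!any(s > 0) || !any(s < 0)) {
      stop("a frame has an empty leaflet; check membrane centering", call. = FALSE)
    }
    mean(zrel[s > 0]) - mean(zrel[s < 0])
  }, numeric(1))
  tibble::tibble(d_pp = mean(per_frame), se = block_se(per_frame, n_blocks),
                 n_frames = nf)
}

#' P-N headgroup tilt angle
#'
#' Mean angle between the phosphorus-to-nitrogen headgroup vector and the
#' outward membrane normal (+z for the upper leaflet, -z for the lower),
#' per leaflet, in degrees, with block-averaged errors. The P->N vector is
#' taken with the minimal-image convention; leaflets are assigned by the
#' phosphorus z relative to the per-frame membrane COM.
#'
#' @param traj An [fb_trajectory()].
#' @param pn_pairs Tibble with columns `p` and `n`: atom indices of the
#'   paired phosphorus and nitrogen of each lipid.
#' @param n_blocks Blocks for the error estimate.
#' @param convention `"outward"` (default) measures against the outward
#'   normal of each leaflet; `"axis"` measures every vector against +z.
#' @return Tibble with `leaflet`, `tilt` (degrees), `se`.
#' @export
pn_tilt <- function(traj, pn_pairs, n_blocks = 5,
                    convention = c("outward", "axis")) {
  stopifnot(inherits(traj, "fb_trajectory"))
  convention <- match.arg(convention)
  stopifnot(all(c("p", "n") %in% names(pn_pairs)), nrow(pn_pairs) > 0)
  if (anyNA(pn_pairs$p) || anyNA(pn_pairs$n)) {
    stop("unpaired P/N atoms in pn_pairs", call. = FALSE)
  }
  mass <- atom_masses(traj)
  nf <- n_frames(traj)
  acc <- list(upper = matrix(NA_real_, nf, 1), lower = matrix(NA_real_, nf, 1))
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    pos <- frame_coords(traj, f)
    zp <- pos[pn_pairs$p, 3]
    com <- com_z_frame(zp, box[3], mass[pn_pairs$p])
    s <- leaflet_sign(min_image(zp - com, box[3]))
    v <- vapply(1:3, function(a) {
      min_image(pos[pn_pairs$n, a] - pos[pn_pairs$p, a], box[a])
    }, numeric(nrow(pn_pairs)))
    if (nrow(pn_pairs) == 1L) v <- matrix(v, nrow = 1L)
    cosang <- v[, 3] / sqrt(rowSums(v^2))
    if (convention == "outward") cosang <- cosang * s
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    acc$upper[f, 1] <- mean(ang[s > 0])
    acc$lower[f, 1] <- mean(ang[s < 0])
  }
  purrr::map_dfr(c("lower", "upper"), function(lf) {
    series <- acc[[lf]][, 1]
    tibble::tibble(leaflet = lf, tilt = mean(series, na.rm = TRUE),
                   se = block_se(series[!is.na(series)], n_blocks))
  })
}

#' Deuterium order parameters of acyl chains
#'
#' S_CD = <(3 cos^2 theta - 1) / 2> with theta the angle between each C-H
#' bond and the membrane normal (z axis), averaged over equivalent
#' hydrogens, lipids and frames, reported per carbon index with
#' block-averaged errors. Requires explicit hydrogens.
#'
#' @param traj An [fb_trajectory()].
#' @param ch_pairs Tibble with columns `chain`, `carbon` (index along the
#'   chain), `c` and `h` (atom indices of the bonded pair).
#' @param n_blocks Blocks for the error estimate.
#' @return Tibble with `chain`, `carbon`, `scd`, `se`.
#' @export
order_parameters <- function(traj, ch_pairs, n_blocks = 5) {
  stopifnot(inherits(traj, "fb_trajectory"))
  stopifnot(all(c("chain", "carbon", "c", "h") %in% names(ch_pairs)),
            nrow(ch_pairs) > 0)
  if (anyNA(ch_pairs$c) || anyNA(ch_pairs$h)) {
    stop("missing hydrogen or carbon indices in ch_pairs", call. = FALSE)
  }
  nf <- n_frames(traj)
  np <- nrow(ch_pairs)
  scd <- matrix(NA_real_, nf, np)
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    pos <- frame_coords(traj, f)
    v <- vapply(1:3, function(a) {
      min_image(pos[ch_pairs$h, a] - pos[ch_pairs$c, a], box[a])
    }, numeric(np))
    if (np == 1L) v <- matrix(v, nrow = 1L)
    c2 <- (v[, 3]^2) / rowSums(v^2)
    scd[f, ] <- (3 * c2 - 1) / 2
  }
  groups <- dplyr::group_split(dplyr::group_by(
    dplyr::mutate(ch_pairs, .col = dplyr::row_number()),
    .data$chain, .data$carbon))
  purrr::map_dfr(groups, function(g) {
    series <- rowMeans(scd[, g$.col, drop = FALSE])
    tibble::tibble(chain = g$chain[1], carbon = g$carbon[1],
                   scd = mean(series), se = block_se(series, n_blocks))
  })
}

#' Membrane center-of-mass drift
#'
#' Tracks the z coordinate of the membrane center of mass over time. The COM
#' is unwrapped continuously across frames (minimal-image increments), so
#' drift through the periodic boundary appears as a smooth line rather than
#' box-size jumps; a wrapped copy is reported alongside the box height.
#'
#' @param traj An [fb_trajectory()].
#' @param selection Membrane atom indices.
#' @return Tibble of class `fb_drift`: `time_ns`, `com_z` (wrapped, nm),
#'   `com_z_unwrapped` (nm), `box_lz` (nm). A `unit_mass` attribute flags
#'   whether unit masses were used because no masses were available.
#' @export
com_drift <- function(traj, selection) {
  stopifnot(inherits(traj, "fb_trajectory"))
  sel <- resolve_selection(traj, selection, "membrane selection")
  mass <- atom_masses(traj)
  unit_mass <- is.null(mass)
  nf <- n_frames(traj)
  com <- vapply(seq_len(nf), function(f) {
    com_z_frame(traj$coords[f, sel, 3], traj$box[f, 3], mass[sel])
  }, numeric(1))
  unwrapped <- com
  for (f in seq_len(nf)[-1]) {
    step <- min_image(com[f] - com[f - 1], traj$box[f, 3])
    unwrapped[f] <- unwrapped[f - 1] + step
  }
  out <- tibble::new_tibble(
    tibble::tibble(
      time_ns = traj$times / 1000,
      com_z = com,
      com_z_unwrapped = unwrapped,
      box_lz = traj$box[, 3]
    ),
    class = "fb_drift"
  )
  attr(out, "unit_mass") <- unit_mass
  if (unit_mass) {
    message("no atom masses available; using unit masses for the COM")
  }
  out
}

#' @export
autoplot.fb_drift <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$com_z_unwrapped,
                                    colour = "membrane COM z")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$box_lz, colour = "box Lz")) +
    ggplot2::labs(x = "time (ns)", y = "z (nm)", colour = NULL)
}

#' Summary table of membrane metrics
#'
#' Convenience wrapper computing APL, D_P-P and P-N tilt in one call,
#' mirroring the usual membrane-comparison table layout.
#'
#' @param traj An [fb_trajectory()].
#' @param p_selection Phosphorus atom indices.
#' @param pn_pairs Tibble of P/N index pairs (see [pn_tilt()]).
#' @param lipids_per_leaflet Non-cholesterol lipid count per leaflet.
#' @param n_blocks Blocks for error estimates.
#' @return Tibble with columns `metric`, `leaflet`, `value`, `se`, `unit`.
#' @export
membrane_metrics <- function(traj, p_selection, pn_pairs, lipids_per_leaflet,
                             n_blocks = 5) {
  apl <- area_per_lipid(traj, lipids_per_leaflet, n_blocks)
  thick <- membrane_thickness(traj, p_selection, n_blocks)
  tilt <- pn_tilt(traj, pn_pairs, n_blocks)
  dplyr::bind_rows(
    tibble::tibble(metric = "APL", leaflet = apl$leaflet,
                   value = apl$apl, se = apl$se, unit = "A^2"),
    tibble::tibble(metric = "D_P-P", leaflet = "both",
                   value = thick$d_pp, se = thick$se, unit = "nm"),
    tibble::tibble(metric = "P-N tilt", leaflet = tilt$leaflet,
                   value = tilt$tilt, se = tilt$se, unit = "deg")
  )
}
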