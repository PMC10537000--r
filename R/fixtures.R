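#' Atomic masses used by the fixture generators (g/mol)
#' @format Named numeric vector.
#' @export
ATOM_MASSES <- c(P = 30.974, N = 14.007, C = 12.011, H = 1.008, O = 15.999,
                 "NA" = 22.990, CL = 35.453, K = 39.098)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a salt-solution ion box for the Brownian calibration analog
#'
#' Places `n_pairs` ion pairs uniformly in the periodic box, excluded from
#' the restrained slab (`|z - z_ref| < r` in the minimal image). Species
#' alternate in a fixed order so runs are bit-reproducible per seed. Water
#' is implicit: in the calibration analog only the restrained solutes are
#' propagated.
#'
#' @param box Box dimensions (nm), e.g. `c(3, 3, 8.3)`.
#' @param n_pairs Number of ion pairs; default 108.
#' @param species Two species labels; default `c("NA", "CL")`.
#' @param restraint An inverted [flat_bottom_restraint()] at the box edge
#'   (`z_ref = 0`); its half-width defines the initial exclusion.
#' @param seed Integer seed.
#' @param side `"both"` (default; ions fill the whole allowed region),
#'   `"lower"` (`z` in `(r, Lz/2)`) or `"upper"` (`(Lz/2, Lz - r)`).
#' @return An object of class `fb_ion_box`: `box`, `particles` (tibble:
#'   `species`, `x`, `y`, `z`, `side`), `restraint`.
#' @export
make_ion_box <- function(box, n_pairs = 108, species = c("NA", "CL"),
                         restraint = flat_bottom_restraint(),
                         seed = 1L, side = c("both", "lower", "upper")) {
  side <- match.arg(side)
  stopifnot(length(box) == 3L, all(box > 0), n_pairs >= 0,
            length(species) == 2L, inherits(restraint, "fb_restraint"))
  Lz <- box[3]
  r <- restraint$r
  lo <- switch(side, both = r, lower = r, upper = Lz / 2)
  hi <- switch(side, both = Lz - r, lower = Lz / 2, upper = Lz - r)
  if (hi <= lo) {
    stop("box too small to place particles outside the restrained region",
         call. = FALSE)
  }
  n <- 2L * as.integer(n_pairs)
  particles <- with_seed(seed, {
    tibble::tibble(
      species = rep(species, n_pairs),
      x = stats::runif(n, 0, box[1]),
      y = stats::runif(n, 0, box[2]),
      z = stats::runif(n, lo, hi)
    )
  })
  particles$side <- ifelse(particles$z < Lz / 2, "lower", "upper")
  out <- list(box = as.numeric(box), particles = particles,
              restraint = restraint)
  class(out) <- "fb_ion_box"
  out
}

#' @export
print.fb_ion_box <- function(x, ...) {
  cat(sprintf("<fb_ion_box> %d particles in %s nm box, restraint r = %g, k = %g\n",
              nrow(x$particles), paste(signif(x$box, 4), collapse = " x "),
              x$restraint$r, x$restraint$k))
  invisible(x)
}

#' Convert an ion box to a GRO-writable structure
#'
#' @param system An `fb_ion_box`.
#' @return An `fb_structure` tibble (one residue per ion).
#' @export
ion_box_structure <- function(system) {
  stopifnot(inherits(system, "fb_ion_box"))
  p <- system$particles
  out <- tibble::tibble(
    resid = seq_len(nrow(p)), resname = p$species, name = p$species,
    atomnum = seq_len(nrow(p)), x = p$x, y = p$y, z = p$z
  )
  out <- tibble::new_tibble(out, class = "fb_structure")
  attr(out, "title") <- "ion box fixture"
  attr(out, "box") <- system$box
  out
}

#' Specification of a synthetic bilayer-like trajectory
#'
#' The bilayer fixtures encode observables, not physics: every structural
#' parameter an analyzer should recover is set explicitly, and the generated
#' trajectory carries a ground-truth record for tests.
#'
#' @param lipids_per_leaflet Lipids in each leaflet.
#' @param p_separation Distance between the mean P planes (nm) — the target
#'   D_P-P.
#' @param p_sigma Gaussian noise on P z-positions (nm).
#' @param pn_tilt_deg Target P-N tilt from the outward normal, degrees
#'   (recycled over leaflets).
#' @param pn_length P-N distance (nm).
#' @param scd_targets Per-carbon target deuterium order parameters, each in
#'   `[-0.5, 1]`; two chains per lipid share the targets.
#' @param n_waters Water molecules (3-site, rigid geometry).
#' @param dipole_field Function of centered z returning the target dipole
#'   cosine in `[-1, 1]`; used when `dipole_mode = "field"`.
#' @param dipole_mode `"field"` (cosines set exactly to the field value) or
#'   `"isotropic"` (uniform random orientations).
#' @param box Box dimensions (nm).
#' @param drift_velocity Rigid drift of the whole membrane along z (nm/ns).
#' @param seed Integer seed.
#' @return A list of class `fb_bilayer_spec`.
#' @export
bilayer_fixture_spec <- function(lipids_per_leaflet = 36, p_separation = 4,
                                 p_sigma = 0.05, pn_tilt_deg = 67,
                                 pn_length = 0.45,
                                 scd_targets = c(0.22, 0.2, 0.18, 0.15, 0.1, 0.05),
                                 n_waters = 500,
                                 dipole_field = function(z) rep(0, length(z)),
                                 dipole_mode = c("field", "isotropic"),
                                 box = c(6, 6, 10), drift_velocity = 0,
                                 seed = 1L) {
  dipole_mode <- match.arg(dipole_mode)
  stopifnot(p_separation > 0, p_sigma >= 0, lipids_per_leaflet >= 1,
            pn_length > 0, length(box) == 3L)
  if (any(scd_targets < -0.5 | scd_targets > 1)) {
    stop("S_CD targets must lie in [-0.5, 1]", call. = FALSE)
  }
  if (any(pn_tilt_deg < 0 | pn_tilt_deg > 180)) {
    stop("tilt targets must lie in [0, 180] degrees", call. = FALSE)
  }
  out <- list(lipids_per_leaflet = lipids_per_leaflet,
              p_separation = p_separation, p_sigma = p_sigma,
              pn_tilt_deg = rep(pn_tilt_deg, length.out = 2L),
              pn_length = pn_length, scd_targets = scd_targets,
              n_waters = n_waters, dipole_field = dipole_field,
              dipole_mode = dipole_mode, box = as.numeric(box),
              drift_velocity = drift_velocity, seed = as.integer(seed))
  class(out) <- "fb_bilayer_spec"
  out
}

# unit vectors at a fixed polar angle from `axis` (rows), random azimuth
tilted_unit_vectors <- function(axis_z_sign, cos_theta, n) {
  phi <- stats::runif(n, 0, 2 * pi)
  sin_theta <- sqrt(pmax(0, 1 - cos_theta^2))
  cbind(sin_theta * cos(phi), sin_theta * sin(phi),
        cos_theta * axis_z_sign)
}

# draw C-H cosines whose squared value has expectation (2 S + 1) / 3 exactly
draw_ch_cos <- function(scd, n) {
  q_mean <- (2 * scd + 1) / 3
  h <- pmin(0.15, q_mean, 1 - q_mean)
  q <- stats::runif(n, q_mean - h, q_mean + h)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  sign * sqrt(q)
}

OH_LENGTH <- 0.09572        # nm, rigid 3-site water geometry
HOH_HALF_ANGLE <- 104.52 / 2 * pi / 180

# rigid water hydrogens given O positions and unit dipole directions
water_hydrogens <- function(o_pos, dipole) {
  n <- nrow(o_pos)
  # random unit vector perpendicular to the dipole
  raw <- matrix(stats::rnorm(3 * n), n, 3)
  raw <- raw - dipole * rowSums(raw * dipole)
  perp <- raw / sqrt(rowSums(raw^2))
  hdir1 <- cos(HOH_HALF_ANGLE) * dipole + sin(HOH_HALF_ANGLE) * perp
  hdir2 <- cos(HOH_HALF_ANGLE) * dipole - sin(HOH_HALF_ANGLE) * perp
  list(h1 = o_pos + OH_LENGTH * hdir1, h2 = o_pos + OH_LENGTH * hdir2)
}

#' Generate a synthetic bilayer-like trajectory with known observables
#'
#' Builds `n_frames` independent frames around the spec's construction:
#' phosphorus planes at +/- separation/2 (Gaussian noise), P-N headgroup
#' vectors at the target tilt from each leaflet's outward normal, acyl-chain
#' C-H bonds drawn so each carbon's expected S_CD equals its target, and
#' rigid 3-site waters with dipole cosines following the requested field.
#' The membrane is centred at `Lz/2` (plus any prescribed drift).
#'
#' @param spec An [bilayer_fixture_spec()].
#' @param n_frames Number of frames; frame spacing is 1 ns.
#' @return An [fb_trajectory()] with a `ground_truth` attribute: the spec
#'   plus `pn_pairs`, `ch_pairs`, `waters` index tibbles, per-leaflet lipid
#'   counts and the implied APL.
#' @export
make_bilayer_trajectory <- function(spec, n_frames = 50) {
  stopifnot(inherits(spec, "fb_bilayer_spec"), n_frames >= 1)
  nl <- spec$lipids_per_leaflet
  ncarb <- length(spec$scd_targets)
  box <- spec$box
  zc0 <- box[3] / 2
  # per-lipid atoms: P, N, then (C, H, H) per carbon on each of two chains
  atoms_per_lipid <- 2L + 2L * ncarb * 3L
  n_lipids <- 2L * nl
  lipid_names <- c("P", "N", unlist(lapply(c("A", "B"), function(ch) {
    as.vector(rbind(paste0("C", ch, seq_len(ncarb)),
                    paste0("H", ch, seq_len(ncarb), "R"),
                    paste0("H", ch, seq_len(ncarb), "S")))
  })))
  atoms <- tibble::tibble(
    name = c(rep(lipid_names, n_lipids), rep(c("OW", "HW1", "HW2"), spec$n_waters)),
    resname = c(rep("LIP", atoms_per_lipid * n_lipids),
                rep("SOL", 3L * spec$n_waters)),
    resid = c(rep(seq_len(n_lipids), each = atoms_per_lipid),
              rep(n_lipids + seq_len(spec$n_waters), each = 3L))
  )
  atoms$mass <- ATOM_MASSES[substr(atoms$name, 1, 1)]
  natoms <- nrow(atoms)

  p_idx <- which(atoms$name == "P")
  n_idx <- which(atoms$name == "N")
  leaflet <- rep(c(rep("upper", nl), rep("lower", nl)))
  pn_pairs <- tibble::tibble(p = p_idx, n = n_idx, leaflet = leaflet)
  ch_pairs <- dplyr::bind_rows(lapply(c("A", "B"), function(ch) {
    dplyr::bind_rows(lapply(seq_len(ncarb), function(j) {
      cidx <- which(atoms$name == paste0("C", ch, j))
      tibble::tibble(
        chain = paste0("sn", match(ch, c("A", "B"))),
        carbon = j,
        c = rep(cidx, 2L),
        h = c(which(atoms$name == paste0("H", ch, j, "R")),
              which(atoms$name == paste0("H", ch, j, "S")))
      )
    }))
  }))
  waters <- tibble::tibble(
    o = which(atoms$name == "OW"),
    h1 = which(atoms$name == "HW1"),
    h2 = which(atoms$name == "HW2")
  )

  half_w <- spec$p_separation / 2 + 0.8   # water region starts past the headgroups
  if (half_w >= box[3] / 2) stop("box too short for the water region", call. = FALSE)

  coords <- array(NA_real_, c(n_frames, natoms, 3L))
  with_seed(spec$seed, {
    xy <- cbind(stats::runif(n_lipids, 0, box[1]),
                stats::runif(n_lipids, 0, box[2]))
    s <- ifelse(leaflet == "upper", 1, -1)
    tilt <- spec$pn_tilt_deg[ifelse(leaflet == "upper", 2L, 1L)] * pi / 180
    for (f in seq_len(n_frames)) {
      zc <- zc0 + spec$drift_velocity * (f - 1)
      pos <- matrix(NA_real_, natoms, 3L)
      pz <- s * spec$p_separation / 2 + stats::rnorm(n_lipids, 0, spec$p_sigma)
      pos[p_idx, ] <- cbind(xy, pz)
      nvec <- tilted_unit_vectors(s, cos(tilt), n_lipids)
      pos[n_idx, ] <- pos[p_idx, ] + spec$pn_length * nvec
      for (ch in c("A", "B")) {
        for (j in seq_len(ncarb)) {
          cidx <- which(atoms$name == paste0("C", ch, j))
          cz <- s * (spec$p_separation / 2 - 0.15 * j)
          cxy <- xy + matrix(stats::rnorm(2 * n_lipids, 0, 0.05), ncol = 2)
          pos[cidx, ] <- cbind(cxy, cz + stats::rnorm(n_lipids, 0, 0.02))
          for (hn in c("R", "S")) {
            hidx <- which(atoms$name == paste0("H", ch, j, hn))
            u <- tilted_unit_vectors(1, draw_ch_cos(spec$scd_targets[j], n_lipids),
                                     n_lipids)
            pos[hidx, ] <- pos[cidx, ] + 0.109 * u
          }
        }
      }
      if (spec$n_waters > 0) {
        # symmetric water slabs between the headgroups and the box edge
        zrel <- stats::runif(spec$n_waters, half_w, box[3] / 2) *
          ifelse(stats::runif(spec$n_waters) < 0.5, 1, -1)
        o_pos <- cbind(stats::runif(spec$n_waters, 0, box[1]),
                       stats::runif(spec$n_waters, 0, box[2]),
                       zrel)
        cosd <- switch(spec$dipole_mode,
                       field = pmin(1, pmax(-1, spec$dipole_field(zrel))),
                       isotropic = stats::runif(spec$n_waters, -1, 1))
        dip <- tilted_unit_vectors(1, cosd, spec$n_waters)
        hh <- water_hydrogens(o_pos, dip)
        pos[waters$o, ] <- o_pos
        pos[waters$h1, ] <- hh$h1
        pos[waters$h2, ] <- hh$h2
      }
      # shift membrane-centered z into the box and wrap
      pos[, 3] <- wrap_box(pos[, 3] + zc, box[3])
      pos[, 1] <- wrap_box(pos[, 1], box[1])
      pos[, 2] <- wrap_box(pos[, 2], box[2])
      coords[f, , ] <- pos
    }
  })

  traj <- fb_trajectory(coords, times = (seq_len(n_frames) - 1) * 1000,
                        box = box, atoms = atoms)
  attr(traj, "ground_truth") <- list(
    spec = spec,
    thickness = spec$p_separation,
    tilt = spec$pn_tilt_deg,
    scd = tibble::tibble(carbon = seq_len(ncarb), scd = spec$scd_targets),
    apl_A2 = box[1] * box[2] * 100 / nl,
    lipids_per_leaflet = nl,
    pn_pairs = pn_pairs, ch_pairs = ch_pairs, waters = waters,
    p_idx = p_idx,
    membrane_sel = which(atoms$resname == "LIP")
  )
  traj
}

#' Ground truth attached to a fixture trajectory
#' @param traj A trajectory from [make_bilayer_trajectory()].
#' @return The ground-truth list.
#' @export
ground_truth <- function(traj) attr(traj, "ground_truth")

#' Replicate a single-bilayer system into a double-bilayer system
#'
#' Builds the stacked double-bilayer reference construction: the system is
#' copied, the copy rotated 180 degrees about the x axis (through the box
#' centre) and translated by one box height, and the two are concatenated —
#' original atoms first, copy second — in a box of doubled z. Works on a
#' trajectory (every frame replicated) or a single structure.
#'
#' @param x An [fb_trajectory()] or `fb_structure`.
#' @return The replicated object, with `Lz` doubled and atoms doubled.
#' @export
make_double_bilayer <- function(x) UseMethod("make_double_bilayer")

#' @export
make_double_bilayer.fb_trajectory <- function(x) {
  nf <- n_frames(x)
  na <- n_atoms(x)
  if (nf > 1 && stats::sd(x$box[, 3]) > 0) {
    stop("replication requires a constant box", call. = FALSE)
  }
  Ly <- x$box[1, 2]
  Lz <- x$box[1, 3]
  # make molecules whole along z before replication: with the box length
  # doubled, a molecule wrapped across the z edge would otherwise be torn
  # apart (its pieces are no longer minimal-image neighbours in the new box)
  zc <- x$coords[, , 3, drop = FALSE]
  dim(zc) <- c(nf, na)
  if (!is.null(x$atoms) && "resid" %in% names(x$atoms)) {
    ref_atom <- match(x$atoms$resid, x$atoms$resid)  # first atom of each residue
    for (f in seq_len(nf)) {
      zref <- zc[f, ref_atom]
      zc[f, ] <- zref + min_image(zc[f, ] - zref, x$box[f, 3])
    }
  }
  coords <- array(NA_real_, c(nf, 2L * na, 3L))
  coords[, seq_len(na), ] <- x$coords
  coords[, seq_len(na), 3] <- zc
  # the copy is stored as the exact periodic image (-y, -z): negation is
  # exact in floating point, whereas Ly - y and 2 Lz - z round; -y == Ly - y
  # and -z == 2 Lz - z modulo the doubled box, and all analyses are
  # minimal-image based, so out-of-box coordinates are legitimate
  coords[, na + seq_len(na), 1] <- x$coords[, , 1]
  coords[, na + seq_len(na), 2] <- -x$coords[, , 2]
  coords[, na + seq_len(na), 3] <- -zc
  atoms <- if (!is.null(x$atoms)) {
    copy <- x$atoms
    if ("resid" %in% names(copy)) copy$resid <- copy$resid + max(x$atoms$resid)
    dplyr::bind_rows(x$atoms, copy)
  }
  fb_trajectory(coords, x$times,
                box = cbind(x$box[, 1], x$box[, 2], 2 * x$box[, 3]),
                atoms = atoms, restraint = x$restraint)
}

#' @export
make_double_bilayer.fb_structure <- function(x) {
  box <- attr(x, "box")
  Ly <- box[2]
  Lz <- box[3]
  copy <- x
  copy$y <- wrap_box(Ly - x$y, Ly)
  copy$z <- wrap_box(2 * Lz - x$z, 2 * Lz)
  copy$resid <- copy$resid + max(x$resid)
  copy$atomnum <- copy$atomnum + max(x$atomnum)
  out <- dplyr::bind_rows(tibble::as_tibble(x), tibble::as_tibble(copy))
  out <- tibble::new_tibble(out, class = "fb_structure")
  attr(out, "title") <- paste(attr(x, "title") %||% "structure", "(doubled)")
  attr(out, "box") <- c(box[1], box[2], 2 * Lz)
  out
}
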