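#' Read a fixed-width GRO structure file
#'
#' Parses the fixed-column GRO dialect: residue number (cols 1-5), residue
#' name (6-10), atom name (11-15), atom number (16-20), positions as three
#' 8.3 floats (nm), and optionally velocities as three 8.4 floats (nm/ps).
#'
#' @param path File path.
#' @return A tibble of class `fb_structure` with columns `resid`, `resname`,
#'   `name`, `atomnum`, `x`, `y`, `z` and (if present) `vx`, `vy`, `vz`;
#'   attributes `title` and `box` (numeric, the box line fields).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) {
    stop("malformed GRO file: need title, atom count, atoms and box lines",
         call. = FALSE)
  }
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L) {
    stop("malformed GRO atom-count line: ", lines[2], call. = FALSE)
  }
  if (length(lines) < 2L + natoms + 1L) {
    stop("truncated GRO file: expected ", natoms, " atom records", call. = FALSE)
  }
  at <- lines[3:(2 + natoms)]
  if (any(nchar(at) < 44L)) {
    stop("truncated GRO atom record(s)", call. = FALSE)
  }
  num <- function(s) as.numeric(s)
  has_vel <- all(nchar(at) >= 68L)
  out <- tibble::tibble(
    resid = as.integer(substr(at, 1, 5)),
    resname = trimws(substr(at, 6, 10)),
    name = trimws(substr(at, 11, 15)),
    atomnum = as.integer(substr(at, 16, 20)),
    x = num(substr(at, 21, 28)),
    y = num(substr(at, 29, 36)),
    z = num(substr(at, 37, 44))
  )
  if (any(!nzchar(out$resname)) || any(!nzchar(out$name))) {
    stop("GRO atom record with empty residue or atom name", call. = FALSE)
  }
  if (has_vel) {
    out$vx <- num(substr(at, 45, 52))
    out$vy <- num(substr(at, 53, 60))
    out$vz <- num(substr(at, 61, 68))
  }
  box <- as.numeric(strsplit(trimws(lines[3 + natoms]), "\\s+")[[1]])
  out <- tibble::new_tibble(out, class = "fb_structure")
  attr(out, "title") <- lines[1]
  attr(out, "box") <- box
  out
}

#' Write a structure to a fixed-width GRO file
#'
#' Positions are written as fixed 8.3 floats and velocities as 8.4 floats,
#' the column layout that downstream column-splicing tools rely on.
#' Writing then re-reading a file produced by this writer is byte-stable.
#'
#' @param structure An `fb_structure` tibble (see [read_gro()]).
#' @param path Output path.
#' @param title Title line; defaults to the structure's stored title.
#' @return Invisibly, the lines written.
#' @export
write_gro <- function(structure, path, title = NULL) {
  stopifnot(is.data.frame(structure), nrow(structure) > 0)
  title <- title %||% attr(structure, "title") %||% "structure"
  box <- attr(structure, "box")
  if (is.null(box)) stop("structure has no box attribute", call. = FALSE)
  has_vel <- all(c("vx", "vy", "vz") %in% names(structure)) &&
    !anyNA(structure$vx)
  core <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  structure$resid %% 100000L,
                  substr(structure$resname, 1, 5),
                  substr(structure$name, 1, 5),
                  structure$atomnum %% 100000L,
                  structure$x, structure$y, structure$z)
  if (has_vel) {
    core <- paste0(core, sprintf("%8.4f%8.4f%8.4f",
                                 structure$vx, structure$vy, structure$vz))
  }
  lines <- c(title, sprintf("%5d", nrow(structure)), core,
             paste0(sprintf("%10.5f", box), collapse = ""))
  writeLines(lines, path)
  invisible(lines)
}

resolve_structure_selection <- function(structure, selection) {
  if (is.null(selection)) return(seq_len(nrow(structure)))
  if (is.character(selection)) {
    idx <- which(structure$resname %in% selection | structure$name %in% selection)
  } else if (is.logical(selection)) {
    idx <- which(selection)
  } else {
    idx <- as.integer(selection)
  }
  if (length(idx) == 0L) {
    stop("restrained selection resolves to no atoms", call. = FALSE)
  }
  if (any(idx < 1L) || any(idx > nrow(structure))) {
    stop("selection indices out of range", call. = FALSE)
  }
  idx
}

#' Build restraint reference coordinates (z set to zero)
#'
#' Returns a copy of the structure in which the z coordinate of every
#' selected atom is exactly 0, leaving every other field untouched. Written
#' with [write_gro()], only the z column (bytes 37-44) of the selected atom
#' lines differs from the input structure's own GRO output. This is the
#' reference-coordinate file handed to the MD engine so the inverted
#' flat-bottom restraint is centred on the `z = 0` box edge for every
#' restrained atom.
#'
#' @param structure An `fb_structure`.
#' @param selection Atoms to reference: integer indices, logical mask,
#'   character vector matched against residue/atom names, or `NULL` for all
#'   atoms (the column-splice recipe). Must resolve to at least one atom.
#' @return The modified `fb_structure` (idempotent).
#' @export
make_reference_coordinates <- function(structure, selection = NULL) {
  stopifnot(is.data.frame(structure))
  idx <- resolve_structure_selection(structure, selection)
  structure$z[idx] <- 0
  structure
}

#' Column-splice a GRO file into a reference-coordinate file
#'
#' File-level equivalent of [make_reference_coordinates()]: rewrites bytes
#' 37-44 (the z position field) of each selected atom line to `"   0.000"`,
#' leaving every other byte of the file untouched.
#'
#' @param in_path,out_path Input and output file paths.
#' @param selection As in [make_reference_coordinates()].
#' @return Invisibly, `out_path`.
#' @export
reference_coordinate_file <- function(in_path, out_path, selection = NULL) {
  lines <- readLines(in_path)
  structure <- read_gro(in_path)
  idx <- resolve_structure_selection(structure, selection)
  target <- 2L + idx
  substr(lines[target], 37, 44) <- sprintf("%8.3f", 0)
  writeLines(lines, out_path)
  invisible(out_path)
}

#' Emit a position-restraint topology stanza
#'
#' Produces the `[ position_restraints ]` block that applies the inverted
#' flat-bottom restraint to the listed atoms of one moleculetype. Each line
#' reads `i 2 5 -r k`: function type 2 (flat-bottom), geometry 5 (layer
#' along z), with the half-width negated to select the inverted potential.
#' Atomic-ion moleculetypes contain a single atom, so `i = 1`.
#'
#' @param restraint An inverted [flat_bottom_restraint()] with `k > 0`.
#' @param moleculetype Moleculetype name (used in a comment header).
#' @param atom_indices 1-based atom indices within the moleculetype; default
#'   `1L` (an atomic ion). For a larger molecule pass its heavy atoms.
#' @return Character scalar: the stanza text (newline-separated).
#' @export
emit_restraint_stanza <- function(restraint, moleculetype = "ION",
                                  atom_indices = 1L) {
  stopifnot(inherits(restraint, "fb_restraint"))
  if (!restraint$inverted) {
    stop("stanza generation expects the inverted restraint form", call. = FALSE)
  }
  if (restraint$r <= 0 || restraint$k < 0) {
    stop("invalid restraint parameters for stanza", call. = FALSE)
  }
  if (length(atom_indices) == 0L) {
    warning("empty atom index list; emitting an empty block", call. = FALSE)
    body <- character()
  } else {
    atom_indices <- as.integer(atom_indices)
    if (any(atom_indices < 1L)) {
      stop("atom indices are 1-based within the moleculetype", call. = FALSE)
    }
    body <- paste(atom_indices, 2, 5,
                  format(-restraint$r, scientific = FALSE, trim = TRUE),
                  format(restraint$k, scientific = FALSE, trim = TRUE))
  }
  paste(c(sprintf("; flat-bottom layer restraint for moleculetype %s",
                  moleculetype),
          "[ position_restraints ]",
          body), collapse = "\n")
}

#' Parse a position-restraint stanza back into parameters
#'
#' @param text Stanza text from [emit_restraint_stanza()].
#' @return Tibble with columns `i`, `funct`, `geometry`, `r`, `k`.
#' @export
parse_restraint_stanza <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  lines <- lines[!grepl("^\\s*(;|\\[)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(i = integer(), funct = integer(),
                          geometry = integer(), r = numeric(), k = numeric()))
  }
  f <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  tibble::tibble(i = as.integer(f[, 1]), funct = as.integer(f[, 2]),
                 geometry = as.integer(f[, 3]), r = -f[, 4], k = f[, 5])
}

#' Recommend the extra solvent layer for a restrained setup
#'
#' An inverted flat-bottom restraint at the box edge depletes solutes from a
#' slab of width `2 r`; adding a water layer of thickness `r` on each side
#' of the membrane restores the unperturbed solvent extent. The molecule
#' count follows the slab-volume estimate ([extra_water_count()]).
#'
#' @param structure An `fb_structure` (its box provides the cross-section),
#'   or a numeric box vector (nm).
#' @param restraint An [flat_bottom_restraint()].
#' @param rho_w,M_w Water density (kg/m^3) and molar mass (kg/mol).
#' @return Tibble: `thickness_per_side` (nm), `total_thickness` (nm),
#'   `n_water` (integer count).
#' @export
recommend_extra_water <- function(structure, restraint, rho_w = 997,
                                  M_w = 0.018016) {
  box <- if (is.numeric(structure)) structure else attr(structure, "box")
  if (is.null(box) || length(box) < 2L) {
    stop("box cross-section unknown", call. = FALSE)
  }
  if (restraint$r == 0) {
    return(tibble::tibble(thickness_per_side = 0, total_thickness = 0,
                          n_water = 0L))
  }
  sol <- solvent_spec(A_xy = box[1] * box[2], rho_w = rho_w, M_w = M_w)
  n <- extra_water_count(sol, restraint$r)
  tibble::tibble(thickness_per_side = restraint$r,
                 total_thickness = 2 * restraint$r,
                 n_water = as.integer(round(n)))
}

#' Validate initial ion placement against the restraint geometry
#'
#' Before a restrained run, every restrained species must start on its
#' assigned side of the `z_ref = 0` plane, outside the restrained slab and
#' outside the membrane. Sides follow the wrapped-coordinate convention with
#' the membrane at the box centre: "lower" is `z` in `(0, Lz/2)`, "upper" is
#' `(Lz/2, Lz)`.
#'
#' @param structure An `fb_structure` with its box attribute.
#' @param side_map Named character vector mapping species (residue names) to
#'   `"lower"` or `"upper"`. Every species named must exist in the
#'   structure.
#' @param membrane_z Length-2 interval (nm) occupied by the membrane.
#' @param restraint An inverted [flat_bottom_restraint()].
#' @return A list of class `fb_validation`: `pass` (logical), `issues`
#'   (tibble: `species`, `atomnum`, `z`, `issue`), and `notes` (run-input
#'   guidance, including the refcoord scaling caveat).
#' @export
validate_ion_sides <- function(structure, side_map, membrane_z, restraint) {
  stopifnot(is.data.frame(structure), length(membrane_z) == 2L,
            inherits(restraint, "fb_restraint"))
  box <- attr(structure, "box")
  if (is.null(box) || length(box) < 3L) stop("box unknown", call. = FALSE)
  Lz <- box[3]
  if (!all(side_map %in% c("lower", "upper"))) {
    stop('sides must be "lower" or "upper"', call. = FALSE)
  }
  missing_sp <- setdiff(names(side_map), unique(structure$resname))
  if (length(missing_sp)) {
    stop("unknown species in side map: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  issues <- purrr::map_dfr(names(side_map), function(sp) {
    rows <- structure[structure$resname == sp, ]
    zw <- wrap_box(rows$z, Lz)
    side <- ifelse(zw > 0 & zw < Lz / 2, "lower",
                   ifelse(zw > Lz / 2 & zw < Lz, "upper", "on_plane"))
    d <- abs(min_image(zw - restraint$z_ref, Lz))
    in_restr <- d < restraint$r
    in_mem <- rows$z >= membrane_z[1] & rows$z <= membrane_z[2]
    dplyr::bind_rows(
      tibble::tibble(species = sp, atomnum = rows$atomnum[side != side_map[[sp]]],
                     z = rows$z[side != side_map[[sp]]], issue = "wrong_side"),
      tibble::tibble(species = sp, atomnum = rows$atomnum[in_restr],
                     z = rows$z[in_restr], issue = "inside_restrained_region"),
      tibble::tibble(species = sp, atomnum = rows$atomnum[in_mem],
                     z = rows$z[in_mem], issue = "inside_membrane")
    )
  })
  notes <- paste(
    "grompp: set refcoord_scaling = all (or com); with z_ref = 0 the",
    "reference positions are unaffected by pressure-coupling box scaling",
    "unless other position restraints are present, in which case 'all'",
    "behaves as expected for the flat-bottom planes."
  )
  out <- list(pass = nrow(issues) == 0L, issues = issues, notes = notes)
  class(out) <- "fb_validation"
  out
}

#' @export
print.fb_validation <- function(x, ...) {
  cat(sprintf("<fb_validation> %s (%d issue%s)\n",
              if (x$pass) "PASS" else "FAIL", nrow(x$issues),
              if (nrow(x$issues) == 1L) "" else "s"))
  if (!x$pass) print(x$issues)
  invisible(x)
}

#' Assemble the full preparation bundle for a restrained setup
#'
#' Combines the reference-coordinate structure, the per-moleculetype
#' restraint stanzas, the extra-water recommendation and the placement
#' validation report into one object ready to write out.
#'
#' @param structure An `fb_structure`.
#' @param restraint An inverted [flat_bottom_restraint()].
#' @param restrained Selection of restrained atoms (see
#'   [make_reference_coordinates()]); also used per species for stanzas.
#' @param side_map,membrane_z Passed to [validate_ion_sides()]; skipped when
#'   `side_map` is `NULL`.
#' @return A list of class `fb_prep_bundle`: `reference` (structure),
#'   `stanzas` (named character), `extra_water` (tibble), `validation`.
#' @export
prep_bundle <- function(structure, restraint, restrained = NULL,
                        side_map = NULL, membrane_z = NULL) {
  ref <- make_reference_coordinates(structure, restrained)
  idx <- resolve_structure_selection(structure, restrained)
  species <- unique(structure$resname[idx])
  stanzas <- vapply(species, function(sp) {
    # atom indices are 1-based within one molecule of the moleculetype
    first_rid <- structure$resid[intersect(idx, which(structure$resname == sp))][1]
    mol_rows <- which(structure$resname == sp & structure$resid == first_rid)
    local_idx <- match(intersect(mol_rows, idx), mol_rows)
    emit_restraint_stanza(restraint, sp, local_idx)
  }, character(1))
  validation <- if (!is.null(side_map)) {
    validate_ion_sides(structure, side_map, membrane_z, restraint)
  }
  out <- list(reference = ref, stanzas = stanzas,
              extra_water = recommend_extra_water(structure, restraint),
              validation = validation)
  class(out) <- "fb_prep_bundle"
  out
}
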