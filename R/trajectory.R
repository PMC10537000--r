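#' Trajectory container
#'
#' In-memory trajectory: an ordered set of frames, each holding the wrapped
#' positions of the same `N` atoms and the periodic box dimensions. Positions
#' are stored as a dense numeric array with dimensions (frame, atom, axis) in
#' nm; atom metadata is a tibble shared across frames.
#'
#' @param coords Numeric array, dim `c(F, N, 3)` (nm).
#' @param times Numeric vector of length `F`, frame times in ps,
#'   strictly increasing.
#' @param box Either a length-3 vector (constant box, nm) or an `F x 3`
#'   matrix of per-frame box dimensions.
#' @param atoms Tibble with one row per atom (any columns; typically `name`,
#'   `resname`, `resid`, `species`, `mass`). May be `NULL`.
#' @param restraint Optional [flat_bottom_restraint()] that was active during
#'   the run; carried so downstream analyses know the perturbed zone.
#' @return An object of class `fb_trajectory`.
#' @export
fb_trajectory <- function(coords, times, box, atoms = NULL, restraint = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  nf <- dim(coords)[1]
  na <- dim(coords)[2]
  stopifnot(length(times) == nf)
  if (nf > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (is.matrix(box)) {
    stopifnot(nrow(box) == nf, ncol(box) == 3L)
  } else {
    stopifnot(length(box) == 3L)
    box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  }
  if (!is.null(atoms)) {
    atoms <- tibble::as_tibble(atoms)
    stopifnot(nrow(atoms) == na)
  }
  structure(
    list(coords = coords, times = as.numeric(times), box = box,
         atoms = atoms, restraint = restraint),
    class = "fb_trajectory"
  )
}

#' @export
print.fb_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fb_trajectory> %d frames x %d atoms, t = %g..%g ps, box %s nm\n",
    n_frames(x), n_atoms(x), x$times[1], x$times[n_frames(x)],
    paste(signif(x$box[1, ], 4), collapse = " x ")
  ))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj An [fb_trajectory()].
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Positions of one frame
#' @param traj An [fb_trajectory()].
#' @param i Frame index (1-based).
#' @return `N x 3` matrix of wrapped positions (nm).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Select atoms of a trajectory by metadata
#'
#' Filters the atom metadata tibble with dplyr-style expressions and returns
#' the matching atom indices.
#'
#' @param traj An [fb_trajectory()] with an `atoms` tibble.
#' @param ... Filter expressions evaluated in the atom tibble, e.g.
#'   `name == "P"`, `species %in% c("NA", "CL")`.
#' @return Integer vector of atom indices.
#' @examples
#' \dontrun{atom_select(traj, resname == "POPC", name == "P")}
#' @export
atom_select <- function(traj, ...) {
  stopifnot(inherits(traj, "fb_trajectory"))
  if (is.null(traj$atoms)) stop("trajectory has no atom metadata", call. = FALSE)
  at <- dplyr::mutate(traj$atoms, .idx = dplyr::row_number())
  dplyr::filter(at, ...)$.idx
}

resolve_selection <- function(traj, selection, what = "selection") {
  if (is.logical(selection)) selection <- which(selection)
  sel <- as.integer(selection)
  if (length(sel) == 0L) stop(sprintf("empty %s", what), call. = FALSE)
  if (any(sel < 1L) || any(sel > n_atoms(traj))) {
    stop(sprintf("%s indices out of range", what), call. = FALSE)
  }
  sel
}

#' Minimal-image convention helpers
#'
#' `min_image()` maps a coordinate difference into `(-L/2, L/2]`;
#' `wrap_box()` maps a coordinate into `[0, L)`.
#'
#' @param d,x Numeric values (nm).
#' @param L Box length (nm).
#' @return Numeric of the same length.
#' @export
min_image <- function(d, L) d - L * round(d / L)

#' @rdname min_image
#' @export
wrap_box <- function(x, L) {
  y <- x %% L
  ifelse(y < 0, y + L, y)
}
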