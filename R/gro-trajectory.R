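#' Read a concatenated multi-frame GRO file as a trajectory
#'
#' A common lightweight trajectory format: whole GRO frames (title, atom
#' count, atom records, box line) appended back to back in one file. All
#' frames must contain the same atoms in the same order. Frame times are
#' taken from a `t=` tag in the title line when present, otherwise frames
#' are numbered 0, 1, 2, ... ps.
#'
#' @param path File path.
#' @return An [fb_trajectory()]; atom metadata (`resid`, `resname`, `name`,
#'   `mass` where the element is recognised) comes from the first frame.
#' @export
read_gro_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  i <- 1L
  while (i + 1L <= length(lines)) {
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed frame header at line ", i, call. = FALSE)
    last <- i + 2L + natoms
    if (last > length(lines)) stop("truncated trajectory frame", call. = FALSE)
    at <- lines[(i + 2L):(i + 1L + natoms)]
    frames[[length(frames) + 1L]] <- list(
      title = lines[i], atoms = at,
      box = as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1]])
    )
    tmatch <- regmatches(lines[i], regexpr("t=\\s*[-0-9.eE+]+", lines[i]))
    times <- c(times, if (length(tmatch)) {
      as.numeric(sub("t=\\s*", "", tmatch))
    } else {
      length(frames) - 1
    })
    i <- last + 1L
  }
  if (length(frames) == 0L) stop("no frames found", call. = FALSE)
  natoms <- length(frames[[1]]$atoms)
  if (any(vapply(frames, function(f) length(f$atoms), integer(1)) != natoms)) {
    stop("frames with inconsistent atom counts", call. = FALSE)
  }
  coords <- array(NA_real_, c(length(frames), natoms, 3L))
  box <- matrix(NA_real_, length(frames), 3L)
  for (f in seq_along(frames)) {
    at <- frames[[f]]$atoms
    coords[f, , 1] <- as.numeric(substr(at, 21, 28))
    coords[f, , 2] <- as.numeric(substr(at, 29, 36))
    coords[f, , 3] <- as.numeric(substr(at, 37, 44))
    box[f, ] <- frames[[f]]$box[1:3]
  }
  at1 <- frames[[1]]$atoms
  atoms <- tibble::tibble(
    resid = as.integer(substr(at1, 1, 5)),
    resname = trimws(substr(at1, 6, 10)),
    name = trimws(substr(at1, 11, 15))
  )
  el <- substr(atoms$name, 1, 1)
  if (all(el %in% names(ATOM_MASSES))) atoms$mass <- ATOM_MASSES[el]
  fb_trajectory(coords, times, box, atoms)
}

#' Write a trajectory as concatenated GRO frames
#'
#' @param traj An [fb_trajectory()] with atom metadata.
#' @param path Output path.
#' @param title Base title; the frame time is appended as `t=<ps>`.
#' @return Invisibly, `path`.
#' @export
write_gro_trajectory <- function(traj, path, title = "frame") {
  stopifnot(inherits(traj, "fb_trajectory"), !is.null(traj$atoms))
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    pos <- frame_coords(traj, f)
    lines <- c(
      sprintf("%s t= %g", title, traj$times[f]),
      sprintf("%5d", n_atoms(traj)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              (at$resid %||% seq_len(nrow(at))) %% 100000L,
              substr(at$resname %||% "MOL", 1, 5),
              substr(at$name %||% "X", 1, 5),
              seq_len(nrow(at)) %% 100000L,
              pos[, 1], pos[, 2], pos[, 3]),
      paste0(sprintf("%10.5f", traj$box[f, ]), collapse = "")
    )
    writeLines(lines, con)
  }
  invisible(path)
}
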