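#' Construct a molecular topology
#'
#' A `topology` holds the static description of the system: one row per atom
#' plus a bond list. Atom ids must be the dense sequence `1:n`.
#'
#' @param atoms data.frame with columns `atom_id` (integer, dense 1..n),
#'   `name`, `element`, `mass` (amu, > 0), `residue_name`, `residue_index`,
#'   `molecule_id`, and `group_tag` (one of `"hydrophobic_tail"`,
#'   `"hydrophilic_head"`, `"water"`, `"bead"`, `"other"`).
#' @param bonds two-column integer matrix (or data.frame) of bonded atom-id
#'   pairs; may be empty.
#' @return object of class `topology`.
#' @export
topology <- function(atoms, bonds = matrix(integer(0), ncol = 2)) {
  req <- c("atom_id", "name", "element", "mass", "residue_name",
           "residue_index", "molecule_id", "group_tag")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (!identical(as.integer(atoms$atom_id), seq_len(n))) {
    stop("atom_id must be the dense sequence 1:", n)
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("all masses must be finite and > 0")
  }
  tags <- c("hydrophobic_tail", "hydrophilic_head", "water", "bead", "other")
  if (!all(atoms$group_tag %in% tags)) {
    stop("group_tag must be one of: ", paste(tags, collapse = ", "))
  }
  bonds <- as.matrix(bonds)
  if (length(bonds)) {
    storage.mode(bonds) <- "integer"
    if (ncol(bonds) != 2L) stop("bonds must have two columns")
    if (any(bonds < 1L | bonds > n)) stop("bonds reference non-existent atoms")
  } else {
    bonds <- matrix(integer(0), ncol = 2)
  }
  structure(list(atoms = atoms, bonds = bonds), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d molecules, %d bonds\n",
              nrow(x$atoms), length(unique(x$atoms$molecule_id)), nrow(x$bonds)))
  tab <- table(x$atoms$group_tag)
  cat("  group_tag:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a `topology`.
#' @return integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Construct a single trajectory frame
#'
#' @param coords n x 3 numeric matrix of coordinates, Angstrom.
#' @param box numeric length-3 vector of orthorhombic edge lengths, Angstrom.
#' @param time frame time, ps.
#' @param velocities optional n x 3 matrix, Angstrom/ps.
#' @return object of class `frame`.
#' @export
new_frame <- function(coords, box, time = 0, velocities = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be n x 3")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive orthorhombic edge lengths")
  }
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!identical(dim(velocities), dim(coords))) {
      stop("velocities, when present, must cover every atom")
    }
  }
  structure(list(time = as.numeric(time), box = box, coords = coords,
                 velocities = velocities), class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("frame: t = %g ps, %d atoms, box %.3f x %.3f x %.3f A%s\n",
              x$time, nrow(x$coords), x$box[1], x$box[2], x$box[3],
              if (is.null(x$velocities)) "" else ", with velocities"))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param top a `topology`.
#' @param frames list of `frame` objects with strictly increasing times and a
#'   constant atom count matching the topology.
#' @param dt time between stored frames, ps; inferred from frame times when
#'   `NULL`.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(top, frames, dt = NULL) {
  if (!inherits(top, "topology")) stop("top must be a topology")
  if (!length(frames)) stop("trajectory needs at least one frame")
  n <- n_atoms(top)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != n) {
      stop("frame ", i, " atom count (", nrow(frames[[i]]$coords),
           ") does not match topology (", n, ")")
    }
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1L) {
    d <- diff(times)
    if (any(d <= 0)) stop("frame times must be strictly increasing")
    if (is.null(dt)) dt <- d[1]
    if (any(abs(d - dt) > 1e-6 * max(dt, 1))) stop("dt must be uniform")
  } else if (is.null(dt)) dt <- 1
  if (dt <= 0) stop("dt must be > 0")
  structure(list(topology = top, frames = frames, dt = dt), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, dt = %g ps, %d atoms\n",
              length(x$frames), x$dt, n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)
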