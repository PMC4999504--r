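# Periodic-boundary geometry. Orthorhombic boxes only: every distance in the
# package goes through the minimum-image convention defined here.

#' Minimum-image displacement between two points
#'
#' Returns the displacement `a - b` wrapped into the primary image, each
#' component in `(-edge/2, +edge/2]`. Its length is the minimum distance over
#' all periodic images of an orthorhombic box.
#'
#' @param a,b numeric 3-vectors or n x 3 matrices of positions, Angstrom.
#' @param box orthorhombic box edge lengths, length-3 numeric, all > 0.
#' @return displacement(s), same shape as the broadcast of `a` and `b`.
#' @export
minimum_image_displacement <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box edges must be > 0")
  a <- if (is.matrix(a)) a else matrix(a, ncol = 3)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 3)
  d <- sweep_rows(a, b)
  for (k in 1:3) {
    d[, k] <- d[, k] - box[k] * ceiling(d[, k] / box[k] - 0.5)
  }
  if (nrow(d) == 1L) drop(d) else d
}

# row-wise a - b with recycling of a single row
sweep_rows <- function(a, b) {
  if (nrow(a) == nrow(b)) return(a - b)
  if (nrow(b) == 1L) return(sweep(a, 2, as.numeric(b), "-"))
  if (nrow(a) == 1L) return(sweep(-b, 2, -as.numeric(a), "-"))
  stop("incompatible shapes")
}

#' Minimum-image distances between two point sets
#'
#' @param a n x 3 matrix; `b` m x 3 matrix; `box` edge lengths.
#' @param a,b coordinate matrices (rows are points), Angstrom.
#' @param box orthorhombic box edges, Angstrom.
#' @return n x m matrix of minimum-image distances.
#' @export
min_image_dist <- function(a, b, box) {
  a <- if (is.matrix(a)) a else matrix(a, ncol = 3)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 3)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * ceiling(dk / box[k] - 0.5)
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Wrap coordinates into the primary box [0, edge)
#'
#' @param coords n x 3 matrix, Angstrom.
#' @param box orthorhombic box edges, Angstrom.
#' @return wrapped n x 3 matrix.
#' @export
wrap_coords <- function(coords, box) {
  for (k in 1:3) coords[, k] <- coords[, k] - box[k] * floor(coords[, k] / box[k])
  coords
}

#' Unwrap the atoms of one molecule across periodic boundaries
#'
#' Breadth-first traversal of the bond graph, placing each atom at the
#' minimum-image position relative to its already-placed bonded neighbour.
#' Atoms of the molecule that are not reachable through bonds are left at
#' their minimum image relative to the first atom.
#'
#' @param coords n x 3 coordinate matrix for the whole system.
#' @param atom_ids ids of the molecule's atoms.
#' @param bonds two-column bond matrix (global atom ids).
#' @param box box edges.
#' @return length(atom_ids) x 3 matrix of unwrapped coordinates, rows in the
#'   order of `atom_ids`.
#' @export
unwrap_molecule <- function(coords, atom_ids, bonds, box) {
  idx <- match(atom_ids, atom_ids)
  local <- stats::setNames(seq_along(atom_ids), atom_ids)
  out <- coords[atom_ids, , drop = FALSE]
  n <- length(atom_ids)
  if (n == 1L) return(out)
  adj <- vector("list", n)
  if (length(bonds)) {
    keep <- bonds[, 1] %in% atom_ids & bonds[, 2] %in% atom_ids
    bl <- bonds[keep, , drop = FALSE]
    for (r in seq_len(nrow(bl))) {
      i <- local[[as.character(bl[r, 1])]]
      j <- local[[as.character(bl[r, 2])]]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  placed <- logical(n)
  placed[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[i]]) {
      if (!placed[j]) {
        out[j, ] <- out[i, ] + minimum_image_displacement(out[j, ], out[i, ], box)
        placed[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  if (!all(placed)) {
    for (j in which(!placed)) {
      out[j, ] <- out[1, ] + minimum_image_displacement(out[j, ], out[1, ], box)
    }
  }
  out
}

#' Unwrap a set of points connected by proximity across periodic boundaries
#'
#' Builds a contact graph (pairs closer than `cutoff` under minimum image) and
#' unwraps each connected point next to an already-placed neighbour. Used to
#' measure spans of aggregates that straddle the boundary; for an aggregate
#' that is itself periodic along an axis the unwrapped extent along that axis
#' reaches (and can exceed) the box edge.
#'
#' @param coords n x 3 matrix of member coordinates.
#' @param box box edges.
#' @param cutoff contact distance, Angstrom.
#' @return n x 3 matrix of unwrapped coordinates.
#' @export
unwrap_by_contacts <- function(coords, box, cutoff) {
  n <- nrow(coords)
  if (n == 1L) return(coords)
  d <- min_image_dist(coords, coords, box)
  placed <- logical(n); placed[1] <- TRUE
  out <- coords
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(d[i, ] <= cutoff & !placed)
    for (j in nb) {
      out[j, ] <- out[i, ] + minimum_image_displacement(coords[j, ], coords[i, ], box)
      placed[j] <- TRUE
    }
    queue <- c(queue, nb)
  }
  for (j in which(!placed)) {
    out[j, ] <- out[1, ] + minimum_image_displacement(coords[j, ], coords[1, ], box)
  }
  out
}
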