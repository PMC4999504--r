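# Atom <-> bead coupling: CG map container, mass-weighted forward mapping
# with PBC-consistent unwrapping, and back-mapping with an exact
# centre-of-mass restraint.

#' Construct a coarse-grained map
#'
#' @param beads data.frame with columns `bead_id` (dense 1..n), `bead_type`,
#'   and `members` (list column of atom-id vectors, each atom in at most one
#'   bead).
#' @param water_multiplicity water molecules represented by one CG water
#'   bead (MARTINI convention: 4).
#' @return object of class `cg_map`.
#' @export
cg_map <- function(beads, water_multiplicity = 4L) {
  if (!all(c("bead_id", "bead_type", "members") %in% names(beads))) {
    stop("beads needs columns bead_id, bead_type, members")
  }
  all_members <- unlist(beads$members)
  if (anyDuplicated(all_members)) {
    stop("atoms may belong to at most one bead")
  }
  if (water_multiplicity < 1L) stop("water multiplicity must be >= 1")
  structure(list(beads = beads, water_multiplicity = water_multiplicity),
            class = "cg_map")
}

#' Read a CG map from TSV
#'
#' Dialect: tab-separated columns `bead_id`, `bead_type`,
#' `member_atom_ids` (comma-separated integers). Lines starting with `#`
#' are comments.
#'
#' @param path file path.
#' @param water_multiplicity see [cg_map()].
#' @return a `cg_map`.
#' @export
read_cgmap <- function(path, water_multiplicity = 4L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  members <- lapply(strsplit(as.character(df$member_atom_ids), ","),
                    function(s) as.integer(trimws(s)))
  cg_map(data.frame(bead_id = df$bead_id, bead_type = df$bead_type,
                    members = I(members)), water_multiplicity)
}

#' Write a CG map to TSV
#'
#' @param map a `cg_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(map, path) {
  df <- data.frame(
    bead_id = map$beads$bead_id, bead_type = map$beads$bead_type,
    member_atom_ids = vapply(map$beads$members, paste, character(1),
                             collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map an atomistic frame onto coarse-grained beads
#'
#' Bead position = mass-weighted centre of the member atoms, with members
#' unwrapped about their first atom (minimum image) before averaging so
#' boundary-straddling groups map correctly; bead velocities are
#' mass-weighted means when present.
#'
#' @param fr atomistic `frame`.
#' @param top atomistic `topology`.
#' @param map a `cg_map`.
#' @return list with `topology` (bead topology, group_tag `bead`) and
#'   `frame` (bead positions wrapped into the box).
#' @export
forward_map <- function(fr, top, map) {
  nb <- nrow(map$beads)
  pos <- matrix(0, nb, 3)
  vel <- if (!is.null(fr$velocities)) matrix(0, nb, 3) else NULL
  mass <- numeric(nb)
  for (b in seq_len(nb)) {
    ids <- map$beads$members[[b]]
    if (any(ids < 1L | ids > n_atoms(top))) {
      stop("bead ", map$beads$bead_id[b], " references non-existent atoms")
    }
    m <- top$atoms$mass[ids]
    co <- fr$coords[ids, , drop = FALSE]
    ref <- co[1, ]
    disp <- minimum_image_displacement(co, matrix(ref, nrow(co), 3,
                                                  byrow = TRUE), fr$box)
    if (!is.matrix(disp)) disp <- matrix(disp, ncol = 3)
    un <- matrix(ref, nrow(co), 3, byrow = TRUE) + disp
    extent <- apply(un, 2, function(v) diff(range(v)))
    if (any(extent > fr$box / 2)) {
      stop("bead ", map$beads$bead_id[b],
           " members span more than half the box: ill-defined group")
    }
    pos[b, ] <- colSums(un * m) / sum(m)
    mass[b] <- sum(m)
    if (!is.null(vel)) {
      vel[b, ] <- colSums(fr$velocities[ids, , drop = FALSE] * m) / sum(m)
    }
  }
  atoms <- data.frame(
    atom_id = seq_len(nb), name = map$beads$bead_type, element = "B",
    mass = mass, residue_name = map$beads$bead_type,
    residue_index = seq_len(nb), molecule_id = seq_len(nb),
    group_tag = "bead", stringsAsFactors = FALSE)
  list(topology = topology(atoms),
       frame = new_frame(wrap_coords(pos, fr$box), fr$box, time = fr$time,
                         velocities = vel))
}

#' Default back-mapping templates for the synthetic 12-bead PA
#'
#' A stand-in internal geometry per bead type: tail beads (`T*`) expand to
#' four carbons in a short zig-zag, head beads (`H*`) to an N-CA-C-O
#' backbone fragment.
#'
#' @return named list of templates, each a list with `names`, `elements`,
#'   and `offsets` (k x 3 matrix, Angstrom, zero mass-weighted mean).
#' @export
default_backmap_templates <- function() {
  zigzag <- cbind(c(-1.9, -0.65, 0.65, 1.9), c(-0.4, 0.4, -0.4, 0.4), 0)
  tailt <- list(names = c("C1", "C2", "C3", "C4"),
                elements = rep("C", 4), offsets = zigzag)
  bb <- cbind(c(-1.6, -0.3, 1.0, 1.9), c(0.4, -0.4, 0.3, -0.6), 0)
  headt <- list(names = c("N", "CA", "C", "O"),
                elements = c("N", "C", "C", "O"), offsets = bb)
  centre <- function(tp) {
    m <- element_mass(tp$elements)
    tp$offsets <- sweep(tp$offsets, 2, colSums(tp$offsets * m) / sum(m), "-")
    tp
  }
  list(tail = centre(tailt), head = centre(headt))
}

.template_for <- function(templates, bead_type) {
  if (!is.null(templates[[bead_type]])) return(templates[[bead_type]])
  if (grepl("^T", bead_type) && !is.null(templates$tail)) return(templates$tail)
  if (grepl("^H", bead_type) && !is.null(templates$head)) return(templates$head)
  stop("no back-mapping template for bead type '", bead_type, "'")
}

#' Back-map beads to atomistic coordinates
#'
#' Atoms are placed at the template geometry under a random rigid rotation
#' plus Gaussian jitter, then rigidly shifted so the group's mass-weighted
#' centre coincides exactly with the bead position.
#'
#' @param cg_fr coarse-grained `frame`.
#' @param cg_top coarse-grained `topology` (bead types in `name`).
#' @param templates named list of per-bead-type templates, see
#'   [default_backmap_templates()].
#' @param seed RNG seed.
#' @param jitter Gaussian positional jitter SD, Angstrom (default 0.3).
#' @return list with atomistic `topology` and `frame`.
#' @export
back_map <- function(cg_fr, cg_top, templates = default_backmap_templates(),
                     seed, jitter = 0.3) {
  set.seed(seed)
  rows <- list(); xyz <- list()
  aid <- 0L
  for (b in seq_len(n_atoms(cg_top))) {
    tp <- .template_for(templates, cg_top$atoms$name[b])
    k <- nrow(tp$offsets)
    m <- element_mass(tp$elements)
    pts <- tp$offsets %*% t(random_rotation()) +
      matrix(stats::rnorm(3 * k, 0, jitter), k, 3)
    com <- colSums(pts * m) / sum(m)
    pts <- sweep(pts, 2, com, "-")
    pts <- sweep(pts, 2, cg_fr$coords[b, ], "+")
    xyz[[b]] <- pts
    rows[[b]] <- data.frame(
      atom_id = aid + seq_len(k), name = tp$names, element = tp$elements,
      mass = m, residue_name = cg_top$atoms$name[b],
      residue_index = b, molecule_id = cg_top$atoms$molecule_id[b],
      group_tag = cg_top$atoms$group_tag[b], stringsAsFactors = FALSE)
    aid <- aid + k
  }
  atoms <- do.call(rbind, rows)
  atoms$group_tag[atoms$group_tag == "bead"] <- "other"
  list(topology = topology(atoms),
       frame = new_frame(do.call(rbind, xyz), cg_fr$box, time = cg_fr$time))
}
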