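# Structure readers/writers: PDB (CRYST1 + ATOM/HETATM), GRO (fixed width,
# nm -> Angstrom), extended XYZ (comment line "box <a> <b> <c> [time <t>]").
# Orthorhombic boxes only; triclinic input is an explicit unsupported-format
# error. Writers are bit-stable: identical inputs give identical bytes.

#' Default residue-name to group_tag mapping
#'
#' Water residue names map to `water`; palmitoyl-tail residue names to
#' `hydrophobic_tail`; the 20 standard amino acids to `hydrophilic_head`;
#' everything else to `other`. Supply your own named list to
#' [read_structure()] when the simulation uses a different naming scheme.
#'
#' @return named list of character vectors, one per group tag.
#' @export
default_group_map <- function() {
  list(
    water = c("HOH", "SOL", "TIP3", "W", "WAT"),
    hydrophobic_tail = c("PLM", "PAL", "C16", "PALM", "TAIL"),
    hydrophilic_head = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                         "GLY", "HIS", "HSD", "HSE", "ILE", "LEU", "LYS",
                         "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
                         "VAL", "HEAD"),
    bead = c("BEAD", "CG")
  )
}

.apply_group_map <- function(resname, group_map) {
  tag <- rep("other", length(resname))
  for (g in names(group_map)) tag[resname %in% group_map[[g]]] <- g
  tag
}

#' Read a structure file (topology + one frame)
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"gro"`, `"xyz"`; inferred from the file
#'   extension when `NULL`.
#' @param box optional length-3 box override, Angstrom; required when the file
#'   carries no box information.
#' @param group_map residue-name to group_tag mapping, see
#'   [default_group_map()].
#' @return list with elements `topology` and `frame`.
#' @export
read_structure <- function(path, format = NULL, box = NULL,
                           group_map = default_group_map()) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  switch(format,
         pdb = .read_pdb(path, box, group_map),
         gro = .read_gro(path, box, group_map),
         xyz = .read_xyz_structure(path, box, group_map))
}

.finish_structure <- function(df, box, time, group_map, bonds = NULL) {
  tag <- .apply_group_map(df$residue_name, group_map)
  # molecule per residue block (consecutive rows sharing residue_index)
  mol <- cumsum(c(TRUE, diff(df$residue_index) != 0))
  atoms <- data.frame(
    atom_id = seq_len(nrow(df)), name = df$name, element = df$element,
    mass = element_mass(df$element), residue_name = df$residue_name,
    residue_index = df$residue_index, molecule_id = mol, group_tag = tag,
    stringsAsFactors = FALSE)
  top <- topology(atoms, if (is.null(bonds)) matrix(integer(0), ncol = 2) else bonds)
  xyz <- unname(as.matrix(df[, c("x", "y", "z")]))
  list(topology = top, frame = new_frame(xyz, box, time = time))
}

.read_pdb <- function(path, box, group_map) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    f <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                                       substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                                       substr(cr[1], 41, 47), substr(cr[1], 48, 54))))
    if (any(is.na(f[1:3]))) stop("malformed CRYST1 record")
    if (any(abs(f[4:6] - 90) > 1e-3, na.rm = TRUE)) {
      stop("triclinic boxes are unsupported (CRYST1 angles differ from 90)")
    }
    box <- f[1:3]
  }
  if (is.null(box)) stop("no CRYST1 record and no box override supplied")
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (!length(sel)) stop("no ATOM/HETATM records in ", path)
  rec <- lines[sel]
  num <- function(a, b, what, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(substr(rec, a, b)))
    if (!allow_na && anyNA(v)) {
      stop("malformed ", what, " at line ", sel[which(is.na(v))[1]], " of ", path)
    }
    v
  }
  df <- data.frame(
    name = trimws(substr(rec, 13, 16)),
    residue_name = trimws(substr(rec, 18, 21)),
    residue_index = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x coordinate"), y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    element = trimws(substr(rec, 77, 78)), stringsAsFactors = FALSE)
  blank <- df$element == ""
  df$element[blank] <- guess_element(df$name[blank])
  .finish_structure(df, box, 0, group_map)
}

.read_gro <- function(path, box, group_map) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed atom count at line 2 of ", path)
  if (length(lines) < 3L + n) stop("truncated GRO file: expected ", n, " atom lines")
  rec <- lines[3:(2 + n)]
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(substr(rec, a, b)))
    if (anyNA(v)) stop("malformed ", what, " at line ", 2 + which(is.na(v))[1], " of ", path)
    v
  }
  bl <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  if (length(bl) < 3L || anyNA(bl[1:3])) stop("malformed GRO box line")
  if (length(bl) > 3L && any(abs(bl[4:length(bl)]) > 1e-8)) {
    stop("triclinic boxes are unsupported (GRO box line has off-diagonal terms)")
  }
  if (is.null(box)) box <- bl[1:3] * 10  # nm -> Angstrom
  df <- data.frame(
    residue_index = as.integer(num(1, 5, "residue number")),
    residue_name = trimws(substr(rec, 6, 10)),
    name = trimws(substr(rec, 11, 15)),
    x = num(21, 28, "x coordinate") * 10,
    y = num(29, 36, "y coordinate") * 10,
    z = num(37, 44, "z coordinate") * 10,
    stringsAsFactors = FALSE)
  df$element <- guess_element(df$name)
  .finish_structure(df, box, 0, group_map)
}

.parse_xyz_comment <- function(comment, box) {
  toks <- strsplit(trimws(comment), "\\s+")[[1]]
  tm <- 0
  i <- match("box", toks)
  if (!is.na(i) && length(toks) >= i + 3) {
    box <- as.numeric(toks[(i + 1):(i + 3)])
  }
  j <- match("time", toks)
  if (!is.na(j) && length(toks) >= j + 1) tm <- as.numeric(toks[j + 1])
  if (is.null(box) || anyNA(box)) {
    stop("XYZ comment line carries no box and no box override supplied")
  }
  list(box = box, time = tm)
}

.read_xyz_structure <- function(path, box, group_map) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed atom count at line 1 of ", path)
  meta <- .parse_xyz_comment(lines[2], box)
  rec <- lines[3:(2 + n)]
  parts <- strsplit(trimws(rec), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 4L)
  if (length(bad)) stop("malformed XYZ record at line ", 2 + bad[1], " of ", path)
  df <- data.frame(
    name = vapply(parts, `[[`, character(1), 1),
    x = as.numeric(vapply(parts, `[[`, character(1), 2)),
    y = as.numeric(vapply(parts, `[[`, character(1), 3)),
    z = as.numeric(vapply(parts, `[[`, character(1), 4)),
    stringsAsFactors = FALSE)
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z)) {
    stop("malformed XYZ coordinate in ", path)
  }
  df$element <- guess_element(df$name)
  df$residue_name <- "UNK"
  df$residue_index <- seq_len(n)
  .finish_structure(df, meta$box, meta$time, group_map)
}

#' Write a structure file
#'
#' @param top a `topology`.
#' @param fr a `frame`.
#' @param path output path.
#' @param format one of `"pdb"`, `"gro"`, `"xyz"`; inferred from the extension
#'   when `NULL`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, fr, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  a <- top$atoms
  xyz <- fr$coords
  lines <- switch(format,
    pdb = c(
      sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
              fr$box[1], fr$box[2], fr$box[3], 90, 90, 90),
      sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
              a$atom_id %% 100000L, substr(a$name, 1, 4),
              substr(a$residue_name, 1, 4), a$residue_index %% 100000L,
              xyz[, 1], xyz[, 2], xyz[, 3], substr(a$element, 1, 2)),
      "END"),
    gro = c(
      "written by hydrafibre",
      sprintf("%5d", nrow(a)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              a$residue_index %% 100000L, substr(a$residue_name, 1, 5),
              substr(a$name, 1, 5), a$atom_id %% 100000L,
              xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10),
      sprintf("%10.5f%10.5f%10.5f", fr$box[1] / 10, fr$box[2] / 10, fr$box[3] / 10)),
    xyz = .format_xyz_frame(a$element, fr))
  writeLines(lines, path)
  invisible(path)
}

.format_xyz_frame <- function(labels, fr, what = c("coords", "velocities")) {
  what <- match.arg(what)
  m <- fr[[what]]
  c(sprintf("%d", nrow(m)),
    sprintf("box %.6f %.6f %.6f time %.6f", fr$box[1], fr$box[2], fr$box[3], fr$time),
    sprintf("%-4s %15.8f %15.8f %15.8f", labels, m[, 1], m[, 2], m[, 3]))
}
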