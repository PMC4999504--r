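# Trajectory readers/writers: multi-frame extended XYZ (text) and the 32-bit
# CHARMM/NAMD DCD dialect. Velocities ride in a parallel XYZ-multi stream.

#' Read a multi-frame trajectory
#'
#' @param paths one or more file paths, concatenated in order.
#' @param top the matching `topology`.
#' @param format `"xyz"` (multi-frame extended XYZ) or `"dcd"`.
#' @param dt override for the frame spacing, ps; otherwise inferred from XYZ
#'   comment-line times or the DCD header.
#' @param velocity_paths optional parallel XYZ-multi stream read as
#'   velocities (Angstrom/ps), one frame per coordinate frame.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(paths, top, format = NULL, dt = NULL,
                            velocity_paths = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(paths[1]))
  format <- match.arg(format, c("xyz", "dcd"))
  frames <- list()
  for (p in paths) {
    fl <- switch(format, xyz = .read_xyz_frames(p, n_atoms(top)),
                 dcd = .read_dcd_frames(p, n_atoms(top)))
    frames <- c(frames, fl)
  }
  if (!is.null(velocity_paths)) {
    vel <- list()
    for (p in velocity_paths) vel <- c(vel, .read_xyz_frames(p, n_atoms(top)))
    if (length(vel) != length(frames)) {
      stop("velocity stream has ", length(vel), " frames, coordinates have ",
           length(frames))
    }
    for (i in seq_along(frames)) frames[[i]]$velocities <- vel[[i]]$coords
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (is.null(dt)) {
    dt <- if (length(times) > 1L && all(diff(times) > 0)) diff(times)[1] else 1
  }
  for (i in seq_along(frames)) frames[[i]]$time <- (i - 1) * dt
  trajectory(top, frames, dt = dt)
}

.read_xyz_frames <- function(path, n_expected) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed atom count at line ", i, " of ", path)
    if (n != n_expected) {
      stop("atom-count mismatch at frame ", fidx, ": file has ", n,
           ", topology has ", n_expected)
    }
    if (i + 1L + n > length(lines)) {
      warning("truncated final frame dropped (frame ", fidx, " of ", path, ")")
      break
    }
    meta <- .parse_xyz_comment(lines[i + 1L], NULL)
    rec <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rec), "\\s+")
    m <- matrix(as.numeric(vapply(parts, function(p) p[2:4], character(3))),
                ncol = 3, byrow = TRUE)
    if (anyNA(m)) stop("malformed coordinate in frame ", fidx, " of ", path)
    frames[[length(frames) + 1L]] <- new_frame(m, meta$box, time = meta$time)
    i <- i + 2L + n
    fidx <- fidx + 1L
  }
  frames
}

#' Write a trajectory
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @param format `"xyz"` or `"dcd"`.
#' @param velocity_path optional path for a parallel XYZ-multi velocity
#'   stream (requires velocities on every frame).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL, velocity_path = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "dcd"))
  labels <- traj$topology$atoms$element
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    for (fr in traj$frames) writeLines(.format_xyz_frame(labels, fr), con)
  } else {
    .write_dcd(traj, path)
  }
  if (!is.null(velocity_path)) {
    con2 <- file(velocity_path, "w")
    on.exit(close(con2), add = TRUE)
    for (fr in traj$frames) {
      if (is.null(fr$velocities)) stop("trajectory has frames without velocities")
      writeLines(.format_xyz_frame(labels, fr, "velocities"), con2)
    }
  }
  invisible(path)
}

# --- DCD (CHARMM/NAMD, 32-bit Fortran records, native endianness) ------------

.rec <- function(con, payload_writer, nbytes) {
  writeBin(as.integer(nbytes), con, size = 4L)
  payload_writer()
  writeBin(as.integer(nbytes), con, size = 4L)
}

.write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  nfr <- n_frames(traj)
  nat <- n_atoms(traj$topology)
  icntrl <- integer(20)
  icntrl[1] <- nfr          # NSET
  icntrl[2] <- 1L           # ISTART
  icntrl[3] <- 1L           # NSAVC
  icntrl[11] <- 1L          # unit-cell block present
  icntrl[20] <- 24L         # CHARMM version tag
  .rec(con, function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl[1:9], con, size = 4L)
    writeBin(as.numeric(traj$dt), con, size = 4L)  # DELTA as float32
    writeBin(icntrl[11:20], con, size = 4L)
  }, 84L)
  title <- formatC("hydrafibre trajectory", width = -80)
  .rec(con, function() {
    writeBin(1L, con, size = 4L)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84L)
  .rec(con, function() writeBin(nat, con, size = 4L), 4L)
  for (fr in traj$frames) {
    cell <- c(fr$box[1], 0, fr$box[2], 0, 0, fr$box[3])
    .rec(con, function() writeBin(cell, con, size = 8L), 48L)
    for (k in 1:3) {
      .rec(con, function() writeBin(fr$coords[, k], con, size = 4L), 4L * nat)
    }
  }
  invisible(path)
}

.read_rec <- function(con, what, size, n) {
  len <- readBin(con, "integer", 1L, size = 4L)
  if (!length(len)) return(NULL)
  out <- readBin(con, what, n, size = size)
  tail <- readBin(con, "integer", 1L, size = 4L)
  if (!length(tail) || tail != len) stop("corrupt DCD record")
  out
}

.read_dcd_frames <- function(path, n_expected) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  len <- readBin(con, "integer", 1L, size = 4L)
  if (!identical(len, 84L)) stop("not a 32-bit CHARMM/NAMD DCD file: ", path)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD")) stop("not a coordinate DCD file: ", path)
  icntrl1 <- readBin(con, "integer", 9L, size = 4L)
  delta <- readBin(con, "numeric", 1L, size = 4L)
  icntrl2 <- readBin(con, "integer", 10L, size = 4L)
  invisible(readBin(con, "integer", 1L, size = 4L))
  has_cell <- icntrl2[1] == 1L
  ntitle_len <- readBin(con, "integer", 1L, size = 4L)
  ntitle <- readBin(con, "integer", 1L, size = 4L)
  if (ntitle > 0) invisible(readChar(con, 80L * ntitle, useBytes = TRUE))
  invisible(readBin(con, "integer", 1L, size = 4L))
  nat <- .read_rec(con, "integer", 4L, 1L)
  if (nat != n_expected) {
    stop("atom-count mismatch at frame 0: file has ", nat,
         ", topology has ", n_expected)
  }
  frames <- list()
  fidx <- 0L
  dt <- if (is.finite(delta) && delta > 0) delta else 1
  repeat {
    box <- c(1, 1, 1)
    if (has_cell) {
      cell <- .read_rec(con, "numeric", 8L, 6L)
      if (is.null(cell)) break
      box <- cell[c(1, 3, 6)]
    }
    x <- .read_rec(con, "numeric", 4L, nat)
    if (is.null(x)) break
    y <- .read_rec(con, "numeric", 4L, nat)
    z <- .read_rec(con, "numeric", 4L, nat)
    if (length(x) < nat || is.null(y) || is.null(z)) {
      warning("truncated final frame dropped (frame ", fidx, " of ", path, ")")
      break
    }
    frames[[length(frames) + 1L]] <- new_frame(cbind(x, y, z), box,
                                               time = fidx * dt)
    fidx <- fidx + 1L
  }
  frames
}
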