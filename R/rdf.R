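# Pair-correlation and density analyses.

# accept a trajectory or a list(topology, frame) and return a trajectory
.as_traj <- function(x) {
  if (inherits(x, "trajectory")) return(x)
  if (is.list(x) && inherits(x$topology, "topology") && inherits(x$frame, "frame")) {
    return(trajectory(x$topology, list(x$frame), dt = 1))
  }
  stop("expected a trajectory or a list(topology, frame)")
}

#' Radial distribution function g(r)
#'
#' Histogram of minimum-image pair distances between two selections,
#' normalised by ideal-gas shell counts: `g(r) = n(r) / (Nf * n_a * rho_b *
#' 4 pi r^2 dr)` with `rho_b` the mean number density of the b selection.
#' Self pairs are always excluded; same-molecule pairs are excluded by
#' default.
#'
#' @param x a `trajectory` or `list(topology, frame)`.
#' @param sel_a,sel_b selection expressions or atom-id vectors.
#' @param r_max histogram range, Angstrom; must not exceed half the shortest
#'   box edge (minimum-image validity).
#' @param dr bin width, Angstrom.
#' @param exclude_same_molecule drop intramolecular pairs (default TRUE).
#' @return object of class `rdf` with fields `bin_edges`, `r`, `g`,
#'   `pair_counts`, `n_frames`, `n_a`, `n_b`, `rho_b`.
#' @export
compute_rdf <- function(x, sel_a, sel_b, r_max, dr,
                        exclude_same_molecule = TRUE) {
  traj <- .as_traj(x)
  if (dr <= 0) stop("dr must be > 0")
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + dr)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  nf <- n_frames(traj)
  na_tot <- 0; nb_tot <- 0; rho_tot <- 0
  mol <- traj$topology$atoms$molecule_id
  for (fr in traj$frames) {
    if (r_max > min(fr$box) / 2 + 1e-9) {
      stop("r_max (", r_max, ") exceeds half the shortest box edge (",
           min(fr$box) / 2, "): minimum-image violation")
    }
    ia <- .resolve_sel(traj$topology, fr, sel_a, "selection sel_a")
    ib <- .resolve_sel(traj$topology, fr, sel_b, "selection sel_b")
    d <- min_image_dist(fr$coords[ia, , drop = FALSE],
                        fr$coords[ib, , drop = FALSE], fr$box)
    same_atom <- outer(ia, ib, "==")
    d[same_atom] <- NA
    if (exclude_same_molecule) d[outer(mol[ia], mol[ib], "==")] <- NA
    d <- d[!is.na(d) & d < r_max]
    counts <- counts + .bincount(d, edges)
    na_tot <- na_tot + length(ia)
    nb_tot <- nb_tot + length(ib)
    rho_tot <- rho_tot + length(ib) / prod(fr$box)
  }
  n_a <- na_tot / nf; n_b <- nb_tot / nf; rho_b <- rho_tot / nf
  r_lo <- edges[-length(edges)]; r_hi <- edges[-1]
  shell <- 4 / 3 * pi * (r_hi^3 - r_lo^3)
  g <- counts / (nf * n_a * rho_b * shell)
  structure(list(bin_edges = edges, r = (r_lo + r_hi) / 2, g = g,
                 pair_counts = counts, n_frames = nf, n_a = n_a, n_b = n_b,
                 rho_b = rho_b,
                 params = list(r_max = r_max, dr = dr,
                               exclude_same_molecule = exclude_same_molecule)),
            class = "rdf")
}

.bincount <- function(v, edges) {
  if (!length(v)) return(numeric(length(edges) - 1L))
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= length(edges) - 1L]
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Position of the first maximum of an RDF
#'
#' The first local maximum of g(r) exceeding `min_height`, scanning outward.
#'
#' @param rdf an `rdf` object.
#' @param min_height minimum peak height (default 1, the ideal-gas level).
#' @return peak position, Angstrom (bin centre).
#' @export
rdf_first_peak <- function(rdf, min_height = 1) {
  g <- rdf$g
  n <- length(g)
  for (i in 2:(n - 1L)) {
    if (g[i] > min_height && g[i] >= g[i - 1L] && g[i] >= g[i + 1L]) {
      return(rdf$r[i])
    }
  }
  stop("no peak above height ", min_height, " found")
}

#' @export
print.rdf <- function(x, ...) {
  cat(sprintf("rdf: %d bins up to %.2f A, %d frames, n_a = %.1f, n_b = %.1f\n",
              length(x$g), max(x$bin_edges), x$n_frames, x$n_a, x$n_b))
  invisible(x)
}

#' Axial density profile
#'
#' Per-slab mass (g/cc) or number (1/A^3) density of a selection along a box
#' axis, averaged over frames. Slab volume is `dr` times the product of the
#' two orthogonal box edges.
#'
#' @param x a `trajectory` or `list(topology, frame)`.
#' @param sel selection expression or atom ids.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param dr slab thickness, Angstrom.
#' @param mass_weighted mass density in g/cc when TRUE (default), number
#'   density in A^-3 otherwise.
#' @return object of class `density_profile` with `bin_centers`, `density`,
#'   `axis`, `selection`.
#' @export
compute_density_profile <- function(x, sel, axis = c("x", "y", "z"), dr,
                                    mass_weighted = TRUE) {
  traj <- .as_traj(x)
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  if (dr <= 0) stop("dr must be > 0")
  box <- traj$frames[[1]]$box
  edges <- seq(0, box[k], by = dr)
  if (edges[length(edges)] < box[k]) edges <- c(edges, box[k])
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  mass <- traj$topology$atoms$mass
  for (fr in traj$frames) {
    ids <- .resolve_sel(traj$topology, fr, sel)
    u <- fr$coords[ids, k] - box[k] * floor(fr$coords[ids, k] / box[k])
    idx <- findInterval(u, edges, rightmost.closed = TRUE)
    w <- if (mass_weighted) mass[ids] else rep(1, length(ids))
    acc <- acc + as.numeric(tapply(w, factor(idx, levels = seq_len(nb)), sum,
                                   default = 0))
  }
  widths <- diff(edges)
  slab_vol <- widths * prod(box[-k])
  dens <- acc / (n_frames(traj) * slab_vol)
  if (mass_weighted) dens <- dens * hf_constants$amu_g / 1e-24
  structure(list(bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 density = dens, axis = axis,
                 mass_weighted = mass_weighted,
                 selection = if (is.character(sel)) sel else "atom ids"),
            class = "density_profile")
}

#' Cylindrical-radial number distribution about a fibre axis
#'
#' Histogram of minimum-image distances from a (box-axis-aligned) fibre axis,
#' one count column per named species selection, averaged over frames.
#'
#' @param x a `trajectory` or `list(topology, frame)`.
#' @param axis_point a point on the axis, Angstrom.
#' @param axis_dir axis direction; must be (anti)parallel to a box axis so
#'   that minimum-image perpendicular distances are well defined.
#' @param sels named list of selection expressions or id vectors.
#' @param dr annulus width, Angstrom.
#' @param r_max histogram range; default half the shortest perpendicular box
#'   edge.
#' @return data.frame with `r` (annulus centres) and one mean-count column
#'   per species.
#' @export
radial_number_distribution <- function(x, axis_point, axis_dir = c(0, 0, 1),
                                       sels, dr, r_max = NULL) {
  traj <- .as_traj(x)
  if (sqrt(sum(axis_dir^2)) == 0) stop("axis direction must be nonzero")
  u <- abs(axis_dir) / sqrt(sum(axis_dir^2))
  k <- which(u > 0.999)
  if (length(k) != 1L) stop("axis must be aligned with a box axis")
  perp <- setdiff(1:3, k)
  box <- traj$frames[[1]]$box
  if (is.null(r_max)) r_max <- min(box[perp]) / 2
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  out <- matrix(0, nb, length(sels), dimnames = list(NULL, names(sels)))
  for (fr in traj$frames) {
    for (s in seq_along(sels)) {
      ids <- .resolve_sel(traj$topology, fr, sels[[s]])
      d2 <- 0
      for (p in perp) {
        dp <- fr$coords[ids, p] - axis_point[p]
        dp <- dp - box[p] * ceiling(dp / box[p] - 0.5)
        d2 <- d2 + dp^2
      }
      out[, s] <- out[, s] + .bincount(sqrt(d2), edges)
    }
  }
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
             out / n_frames(traj), check.names = FALSE)
}
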