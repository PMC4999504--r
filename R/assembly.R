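# Aggregate census: end-to-end distances, PBC-aware single-linkage
# clustering of molecules, micelle/fibre classification, fibre metrics,
# hexagonal lattice spacing.

#' Per-frame mean end-to-end distance of molecules
#'
#' The distance between two named endpoint atoms of every molecule, after
#' unwrapping each molecule across periodic boundaries via its bond
#' connectivity.
#'
#' @param traj a `trajectory`.
#' @param end_names length-2 character vector of endpoint atom names
#'   (one match of each required per molecule), or a two-column matrix of
#'   atom ids (one row per molecule).
#' @param molecules molecule ids to include; default all molecules that
#'   contain both endpoint names.
#' @return data.frame with `time`, `mean`, `sd` (Angstrom).
#' @export
end_to_end <- function(traj, end_names, molecules = NULL) {
  a <- traj$topology$atoms
  if (is.matrix(end_names)) {
    ep <- end_names
  } else {
    if (is.null(molecules)) molecules <- sort(unique(a$molecule_id))
    ep <- t(vapply(molecules, function(m) {
      i1 <- a$atom_id[a$molecule_id == m & a$name == end_names[1]]
      i2 <- a$atom_id[a$molecule_id == m & a$name == end_names[2]]
      if (length(i1) < 1L || length(i2) < 1L) {
        stop("molecule ", m, " is missing endpoint '",
             if (length(i1) < 1L) end_names[1] else end_names[2], "'")
      }
      c(i1[1], i2[1])
    }, integer(2)))
  }
  out <- data.frame(time = numeric(0), mean = numeric(0), sd = numeric(0))
  for (fr in traj$frames) {
    d <- vapply(seq_len(nrow(ep)), function(r) {
      m <- a$molecule_id[ep[r, 1]]
      ids <- a$atom_id[a$molecule_id == m]
      un <- unwrap_molecule(fr$coords, ids, traj$topology$bonds, fr$box)
      p <- un[match(ep[r, ], ids), , drop = FALSE]
      sqrt(sum((p[1, ] - p[2, ])^2))
    }, numeric(1))
    out <- rbind(out, data.frame(time = fr$time, mean = mean(d),
                                 sd = stats::sd(d)))
  }
  out
}

#' Cluster molecules by single-linkage bead contacts
#'
#' Two molecules join the same aggregate when any pair of their selected
#' beads lies within `cutoff` under the minimum image; clusters are the
#' connected components of that contact graph. Labels are deterministic:
#' ordered by decreasing size, ties broken by the lowest member molecule id.
#'
#' @param fr a `frame`.
#' @param top the matching `topology`.
#' @param sel selection (expression or ids) of the beads that define
#'   contact, e.g. `"group hydrophobic_tail"`.
#' @param cutoff contact distance, Angstrom (6.0 suits CG beads, 4.5
#'   atomistic carbons).
#' @return object of class `cluster_assignment`: data.frame `molecules`
#'   (`molecule_id`, `cluster`), vector `sizes` (aggregation numbers
#'   N_agg), `cutoff`, `sel`.
#' @export
cluster_molecules <- function(fr, top, sel, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ids <- .resolve_sel(top, fr, sel)
  mol <- top$atoms$molecule_id[ids]
  co <- fr$coords[ids, , drop = FALSE]
  d <- min_image_dist(co, co, fr$box)
  adj <- d <= cutoff
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  mols <- sort(unique(mol))
  g <- igraph::make_empty_graph(n = length(mols), directed = FALSE)
  if (nrow(pairs)) {
    e <- cbind(match(mol[pairs[, 1]], mols), match(mol[pairs[, 2]], mols))
    e <- unique(e[e[, 1] != e[, 2], , drop = FALSE])
    if (nrow(e)) g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)$membership
  sz <- table(comp)
  first_mol <- tapply(mols, comp, min)
  ord <- order(-as.numeric(sz), as.numeric(first_mol))
  relabel <- match(comp, as.integer(names(sz))[ord])
  sizes <- as.numeric(sz)[ord]
  structure(list(molecules = data.frame(molecule_id = mols, cluster = relabel),
                 sizes = sizes, cutoff = cutoff,
                 sel = if (is.character(sel)) sel else "atom ids"),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d clusters over %d molecules (cutoff %.1f A)\n",
              length(x$sizes), nrow(x$molecules), x$cutoff))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

# unwrapped member bead coordinates of one cluster (contact-graph unwrap)
.cluster_coords <- function(clusters, which_cluster, fr, top, sel = NULL) {
  mols <- clusters$molecules$molecule_id[clusters$molecules$cluster == which_cluster]
  ids <- top$atoms$atom_id[top$atoms$molecule_id %in% mols]
  if (!is.null(sel)) ids <- intersect(ids, .resolve_sel(top, fr, sel))
  list(ids = ids, mols = mols,
       coords = unwrap_by_contacts(fr$coords[ids, , drop = FALSE], fr$box,
                                   cutoff = max(clusters$cutoff, 6)))
}

#' Classify an aggregate as micelle or fibre
#'
#' Principal axis from the spread of the member coordinates (unwrapped
#' across periodic boundaries by contact connectivity); an aggregate whose
#' extent along that axis reaches `span_frac` of the corresponding box edge
#' is a periodic-spanning fibre, otherwise a micelle. The radius is the RMS
#' radial distance of tail beads from the axis.
#'
#' @param clusters a `cluster_assignment` from [cluster_molecules()].
#' @param which_cluster cluster label to classify.
#' @param fr the `frame`.
#' @param top the `topology`.
#' @param span_frac spanning threshold as a fraction of the box edge
#'   (default 0.9).
#' @return list with `class` (`"micelle"`/`"fibre"`), `axis` (unit vector),
#'   `centroid`, `radius` (Angstrom), `axial_extent` (Angstrom),
#'   `n_molecules`.
#' @export
classify_aggregate <- function(clusters, which_cluster, fr, top,
                               span_frac = 0.9) {
  cc <- .cluster_coords(clusters, which_cluster, fr, top)
  if (length(cc$mols) < 2L) stop("cluster size must be >= 2")
  co <- cc$coords
  cen <- colMeans(co)
  # the axis comes from the tail-bead core when present: head beads spread
  # radially and would tilt a whole-aggregate principal component
  tail_rows <- which(top$atoms$group_tag[cc$ids] == "hydrophobic_tail")
  core <- if (length(tail_rows) >= 3L) co[tail_rows, , drop = FALSE] else co
  pc <- stats::prcomp(core, center = TRUE)
  axis <- pc$rotation[, 1]
  proj <- as.numeric((co - matrix(cen, nrow(co), 3, byrow = TRUE)) %*% axis)
  extent <- diff(range(proj))
  k <- which.max(abs(axis))
  is_fibre <- extent >= span_frac * fr$box[k]
  tail_ids <- top$atoms$atom_id[top$atoms$molecule_id %in% cc$mols &
                                  top$atoms$group_tag == "hydrophobic_tail"]
  rid <- if (length(tail_ids)) match(tail_ids, cc$ids) else seq_len(nrow(co))
  rel <- co[rid, , drop = FALSE] - matrix(cen, length(rid), 3, byrow = TRUE)
  radial <- sqrt(rowSums((rel - outer(as.numeric(rel %*% axis), axis))^2))
  list(class = if (is_fibre) "fibre" else "micelle",
       axis = axis, centroid = wrap_coords(matrix(cen, 1, 3), fr$box)[1, ],
       radius = sqrt(mean(radial^2)), axial_extent = extent,
       n_molecules = length(cc$mols))
}

#' Linear density and diameter of a fibre
#'
#' @param clusters a `cluster_assignment`.
#' @param which_cluster label of a cluster classified as a fibre.
#' @param fr the `frame`.
#' @param top the `topology`.
#' @return list with `linear_density` (PAs per nm of axial box length) and
#'   `diameter` (Angstrom, twice the 95th percentile of member radial
#'   distances from the axis).
#' @export
fibre_metrics <- function(clusters, which_cluster, fr, top) {
  cls <- classify_aggregate(clusters, which_cluster, fr, top)
  if (cls$class != "fibre") {
    stop("cluster ", which_cluster, " is a micelle, not a fibre")
  }
  cc <- .cluster_coords(clusters, which_cluster, fr, top)
  co <- cc$coords
  cen <- colMeans(co)
  rel <- co - matrix(cen, nrow(co), 3, byrow = TRUE)
  radial <- sqrt(rowSums((rel - outer(as.numeric(rel %*% cls$axis), cls$axis))^2))
  k <- which.max(abs(cls$axis))
  list(linear_density = cls$n_molecules / (fr$box[k] / 10),
       diameter = 2 * as.numeric(stats::quantile(radial, 0.95)))
}

#' Nearest-neighbour spacing of fibre centroids
#'
#' @param centroids n x 3 matrix of fibre centroids (n >= 2).
#' @param box box edges.
#' @param coord_factor neighbours within `coord_factor` times the minimum
#'   spacing count toward the coordination number (default 1.2).
#' @return list with `mean_spacing` (Angstrom), `spacings` (per fibre), and
#'   `coordination` (neighbour counts per fibre).
#' @export
lattice_spacing <- function(centroids, box, coord_factor = 1.2) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2L) stop("need at least 2 fibre centroids")
  d <- min_image_dist(centroids, centroids, box)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  coord <- rowSums(d <= coord_factor * min(nn))
  list(mean_spacing = mean(nn), spacings = nn, coordination = coord)
}
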