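# Geometric regions for density targets and measurements: slabs, cylinder
# shells, and the inter-fibre channel of a fibre bundle.

#' Construct a region specification
#'
#' Supported kinds:
#' \describe{
#'   \item{slab}{`axis` (1, 2 or 3), `lo`, `hi` (Angstrom): all points with
#'     the axis coordinate in `[lo, hi)`.}
#'   \item{cylinder_shell}{`axis_point` (3-vector), `axis` (box axis index),
#'     `r_in`, `r_out`: minimum-image perpendicular distance from the axis
#'     in `[r_in, r_out)`.}
#'   \item{inter_fibre}{`axis_points` (n x 2 matrix of fibre axis x-y
#'     positions for z-aligned fibres), `fibre_radius`: points farther than
#'     `fibre_radius` from every fibre axis but within `fibre_radius` of
#'     the segment network connecting neighbouring axes — the water channel
#'     between the fibres.}
#' }
#'
#' @param kind region kind.
#' @param ... kind-specific parameters (see Details).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(kind = c("slab", "cylinder_shell", "inter_fibre"),
                        ...) {
  kind <- match.arg(kind)
  p <- list(...)
  structure(list(kind = kind, params = p), class = "region_spec")
}

# squared min-image perpendicular distance from a z/axis-aligned line
.perp_dist <- function(pts, centre2, box, perp) {
  d2 <- 0
  for (j in seq_along(perp)) {
    dp <- pts[, perp[j]] - centre2[j]
    dp <- dp - box[perp[j]] * ceiling(dp / box[perp[j]] - 0.5)
    d2 <- d2 + dp^2
  }
  sqrt(d2)
}

#' Test points for region membership
#'
#' @param region a `region_spec`.
#' @param pts n x 3 matrix of points, Angstrom.
#' @param box box edges.
#' @return logical vector of length n.
#' @export
region_contains <- function(region, pts, box) {
  pts <- if (is.matrix(pts)) pts else matrix(pts, ncol = 3)
  p <- region$params
  switch(region$kind,
    slab = {
      k <- p$axis
      u <- pts[, k] - box[k] * floor(pts[, k] / box[k])
      u >= p$lo & u < p$hi
    },
    cylinder_shell = {
      perp <- setdiff(1:3, p$axis)
      r <- .perp_dist(pts, p$axis_point[perp], box, perp)
      r >= p$r_in & r < p$r_out
    },
    inter_fibre = {
      ax <- p$axis_points
      rad <- p$fibre_radius
      n <- nrow(ax)
      dmin <- rep(Inf, nrow(pts))
      for (i in seq_len(n)) {
        dmin <- pmin(dmin, .perp_dist(pts, ax[i, ], box, c(1, 2)))
      }
      outside_all <- dmin > rad
      # distance (in x-y, no wrap: the bundle sits inside the box) to the
      # segments joining each pair of neighbouring axes (within 1.5 spacings)
      dseg <- rep(Inf, nrow(pts))
      if (n >= 2L) {
        dd <- as.matrix(stats::dist(ax))
        near <- min(dd[dd > 0])
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          if (dd[i, j] > 1.5 * near) next
          a <- ax[i, ]; b <- ax[j, ]
          ab <- b - a
          tt <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                                   (pts[, 2] - a[2]) * ab[2]) / sum(ab^2)))
          dx <- pts[, 1] - (a[1] + tt * ab[1])
          dy <- pts[, 2] - (a[2] + tt * ab[2])
          dseg <- pmin(dseg, sqrt(dx^2 + dy^2))
        }
      }
      outside_all & dseg <= rad
    })
}

#' Volume of a region
#'
#' Analytic for slabs and cylinder shells; seeded Monte-Carlo integration
#' over the box for the inter-fibre channel.
#'
#' @param region a `region_spec`.
#' @param box box edges.
#' @param n_mc Monte-Carlo sample count (inter_fibre only).
#' @param mc_seed seed for the Monte-Carlo draw (fixed default keeps volumes
#'   deterministic).
#' @return volume in Angstrom^3.
#' @export
region_volume <- function(region, box, n_mc = 2e5, mc_seed = 20210818) {
  p <- region$params
  v <- switch(region$kind,
    slab = (p$hi - p$lo) * prod(box[-p$axis]),
    cylinder_shell = pi * (p$r_out^2 - p$r_in^2) * box[p$axis],
    inter_fibre = {
      set.seed(mc_seed)
      pts <- cbind(stats::runif(n_mc, 0, box[1]), stats::runif(n_mc, 0, box[2]),
                   stats::runif(n_mc, 0, box[3]))
      prod(box) * mean(region_contains(region, pts, box))
    })
  if (!is.finite(v) || v <= 0) stop("region volume must be > 0")
  v
}

#' Mass density of a species within a region
#'
#' Sum of selected-atom masses inside the region divided by the region
#' volume, in g/cc.
#'
#' @param fr a `frame`.
#' @param top the `topology`.
#' @param region a `region_spec`, or `NULL` for the whole box.
#' @param sel selection expression or atom ids.
#' @return density, g/cc.
#' @export
measure_region_density <- function(fr, top, region = NULL, sel = "all") {
  ids <- .resolve_sel(top, fr, sel)
  if (is.null(region)) {
    vol <- prod(fr$box)
    inside <- rep(TRUE, length(ids))
  } else {
    vol <- region_volume(region, fr$box)
    inside <- region_contains(region, fr$coords[ids, , drop = FALSE], fr$box)
  }
  sum(top$atoms$mass[ids[inside]]) * hf_constants$amu_g / (vol * 1e-24)
}
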