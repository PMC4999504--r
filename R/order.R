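# Orientational and translational order parameters of water:
# Steinhardt Q6, the Errington-Debenedetti tetrahedral parameter, and the
# cumulative translational order t.

.op_series <- function(kind, times, values, selection, convention) {
  structure(list(kind = kind, times = times, values = values,
                 selection = selection, convention = convention),
            class = "op_series")
}

#' @export
print.op_series <- function(x, ...) {
  cat(sprintf("op_series [%s]: %d frames, mean = %.4f (convention: %s)\n",
              x$kind, length(x$values), mean(x$values),
              paste(names(x$convention), unlist(x$convention), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# spherical harmonics Y_6m (m = 0..6) for unit vectors u (n x 3);
# returns 7 x n complex matrix. m < 0 follows by conjugation and is
# accounted for in the invariant sums.
.y6m <- function(u) {
  cost <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  P <- pracma::legendre(6, cost)           # 7 x n, Condon-Shortley included
  if (is.null(dim(P))) P <- matrix(P, ncol = 1)
  m <- 0:6
  norm <- sqrt((13 / (4 * pi)) * factorial(6 - m) / factorial(6 + m))
  E <- exp(1i * outer(m, phi))
  (norm * P) * E
}

# neighbour bond vectors of evaluation particle `i` (a row of `eval_co`)
# against the candidate pool; `self` is the pool row to exclude (NA if the
# particle is not in the pool)
.neighbour_vectors <- function(eval_co, pool_co, box, i, conv, self = i) {
  d <- minimum_image_displacement(pool_co, eval_co[i, , drop = FALSE], box)
  if (!is.matrix(d)) d <- matrix(d, ncol = 3)
  dist <- sqrt(rowSums(d^2))
  if (!is.na(self)) dist[self] <- Inf
  if (!is.null(conv$cutoff)) {
    nb <- which(dist <= conv$cutoff)
  } else {
    nb <- order(dist)[seq_len(min(conv$k_nearest, sum(is.finite(dist))))]
  }
  list(idx = nb, vec = d[nb, , drop = FALSE], dist = dist[nb])
}

#' Steinhardt Q6 orientational order parameter
#'
#' Per particle, `q6(i) = sqrt((4 pi / 13) sum_m |<Y_6m(r_ij)>_j|^2)` over
#' the minimum-image bond vectors to its neighbours; the series value is the
#' mean over selected particles per frame. With `global = TRUE` the `Y_6m`
#' averages run over all bonds of all particles before the invariant is
#' formed (the ensemble variant).
#'
#' @param x a `trajectory` or `list(topology, frame)`.
#' @param sel selection expression or atom ids.
#' @param neighbours neighbour convention: `list(cutoff = r)` (Angstrom) or
#'   `list(k_nearest = k)`. Default 3.5 A, the atomistic water-oxygen shell;
#'   use ~6.5 A for coarse-grained beads.
#' @param global use the globally averaged q_6m variant.
#' @param pool selection supplying the neighbour candidates (defaults to
#'   `sel` itself).
#' @return an `op_series` (kind `"q6"`); values in [0, 1]. Isolated
#'   particles are excluded with a message.
#' @export
compute_q6 <- function(x, sel, neighbours = list(cutoff = 3.5),
                       global = FALSE, pool = NULL) {
  traj <- .as_traj(x)
  vals <- numeric(n_frames(traj))
  n_isolated <- 0L
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$frames[[f]]
    ids <- .resolve_sel(traj$topology, fr, sel)
    pool_ids <- if (is.null(pool)) ids else .resolve_sel(traj$topology, fr, pool)
    co <- fr$coords[ids, , drop = FALSE]
    pool_co <- fr$coords[pool_ids, , drop = FALSE]
    qsum <- complex(7)
    nbond <- 0L
    qi <- numeric(0)
    for (i in seq_len(nrow(co))) {
      nb <- .neighbour_vectors(co, pool_co, fr$box, i, neighbours,
                               self = match(ids[i], pool_ids))
      if (!length(nb$idx)) { n_isolated <- n_isolated + 1L; next }
      u <- nb$vec / nb$dist
      Y <- .y6m(u)
      if (global) {
        qsum <- qsum + rowSums(Y)
        nbond <- nbond + length(nb$idx)
      } else {
        ybar <- rowMeans(Y)
        qi <- c(qi, sqrt((4 * pi / 13) *
                           (Mod(ybar[1])^2 + 2 * sum(Mod(ybar[-1])^2))))
      }
    }
    if (global) {
      if (nbond == 0L) stop("all selected particles are isolated")
      ybar <- qsum / nbond
      vals[f] <- sqrt((4 * pi / 13) *
                        (Mod(ybar[1])^2 + 2 * sum(Mod(ybar[-1])^2)))
    } else {
      if (!length(qi)) stop("all selected particles are isolated")
      vals[f] <- mean(qi)
    }
  }
  if (n_isolated > 0L) {
    message(n_isolated, " isolated particle(s) excluded from q6")
  }
  .op_series("q6", vapply(traj$frames, `[[`, numeric(1), "time"), vals,
             if (is.character(sel)) sel else "atom ids",
             c(neighbours, list(global = global)))
}

#' Errington-Debenedetti tetrahedral order parameter
#'
#' Per particle, `q = 1 - (3/8) sum_{j<k} (cos psi_jk + 1/3)^2` over the six
#' angle pairs of its four nearest minimum-image neighbours; 1 for a perfect
#' tetrahedron, 0 on average for random directions (values can be negative,
#' down to -3 for degenerate geometries).
#'
#' @param x a `trajectory` or `list(topology, frame)`.
#' @param sel selection expression or atom ids.
#' @param cutoff neighbour search cutoff, Angstrom; particles with fewer
#'   than four neighbours inside it are excluded with a message. `Inf`
#'   (default) always takes the four nearest.
#' @param pool selection supplying the neighbour candidates (defaults to
#'   `sel` itself).
#' @return an `op_series` (kind `"q_tet"`), values averaged over particles
#'   per frame.
#' @export
compute_tetrahedral_order <- function(x, sel, cutoff = Inf, pool = NULL) {
  traj <- .as_traj(x)
  vals <- numeric(n_frames(traj))
  n_excluded <- 0L
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$frames[[f]]
    ids <- .resolve_sel(traj$topology, fr, sel)
    pool_ids <- if (is.null(pool)) ids else .resolve_sel(traj$topology, fr, pool)
    co <- fr$coords[ids, , drop = FALSE]
    pool_co <- fr$coords[pool_ids, , drop = FALSE]
    if (nrow(pool_co) < 5L) stop("tetrahedral order needs at least 5 particles")
    qi <- numeric(0)
    for (i in seq_len(nrow(co))) {
      nb <- .neighbour_vectors(co, pool_co, fr$box, i, list(k_nearest = 4L),
                               self = match(ids[i], pool_ids))
      if (length(nb$idx) < 4L || max(nb$dist) > cutoff) {
        n_excluded <- n_excluded + 1L
        next
      }
      u <- nb$vec / nb$dist
      s <- 0
      for (j in 1:3) for (k in (j + 1):4) {
        s <- s + (sum(u[j, ] * u[k, ]) + 1 / 3)^2
      }
      qi <- c(qi, 1 - 3 / 8 * s)
    }
    if (!length(qi)) stop("no particle has 4 neighbours within the cutoff")
    vals[f] <- mean(qi)
  }
  if (n_excluded > 0L) {
    message(n_excluded, " particle(s) with < 4 neighbours excluded from q_tet")
  }
  .op_series("q_tet", vapply(traj$frames, `[[`, numeric(1), "time"), vals,
             if (is.character(sel)) sel else "atom ids",
             list(neighbours = "4 nearest", cutoff = cutoff))
}

#' Translational order parameter t
#'
#' `t = (1/xi_c) integral_0^{xi_c} |g(xi) - 1| d xi` with the density-reduced
#' distance `xi = r * rho^(1/3)`, evaluated by trapezoidal quadrature on the
#' RDF grid of the selection with itself. Zero for an ideal gas, large
#' (> 1) for a crystal.
#'
#' @param x a `trajectory` or `list(topology, frame)`.
#' @param sel selection expression or atom ids.
#' @param xi_cutoff upper limit in reduced units (default 2.843).
#' @param dr RDF bin width, Angstrom; default resolves the reduced grid into
#'   ~200 bins.
#' @return an `op_series` (kind `"t_trans"`), one value per frame.
#' @export
compute_translational_order <- function(x, sel, xi_cutoff = 2.843, dr = NULL) {
  traj <- .as_traj(x)
  vals <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$frames[[f]]
    ids <- .resolve_sel(traj$topology, fr, sel)
    rho <- length(ids) / prod(fr$box)
    r_max <- xi_cutoff / rho^(1 / 3)
    if (r_max > min(fr$box) / 2) {
      stop("xi_cutoff needs r up to ", signif(r_max, 4),
           " A, beyond half the shortest box edge: minimum-image violation")
    }
    step <- if (is.null(dr)) r_max / 200 else dr
    one <- trajectory(traj$topology, traj$frames[f], dt = traj$dt)
    rdf <- compute_rdf(one, ids, ids, r_max = r_max, dr = step,
                       exclude_same_molecule = FALSE)
    xi <- rdf$r * rho^(1 / 3)
    integrand <- abs(rdf$g - 1)
    keep <- xi <= xi_cutoff
    vals[f] <- .trapz(xi[keep], integrand[keep]) / xi_cutoff
  }
  .op_series("t_trans", vapply(traj$frames, `[[`, numeric(1), "time"), vals,
             if (is.character(sel)) sel else "atom ids",
             list(xi_cutoff = xi_cutoff))
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
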