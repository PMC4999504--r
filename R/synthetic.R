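# Seeded synthetic generators: every fixture the analyses need, without an MD
# engine. Each generator is a pure function of its parameters and seed.

.single_site_topology <- function(n, element = "O", residue = "HOH",
                                  group = "water", mass = NULL) {
  if (is.null(mass)) mass <- element_mass(element)
  topology(data.frame(
    atom_id = seq_len(n), name = element, element = element, mass = mass,
    residue_name = residue, residue_index = seq_len(n),
    molecule_id = seq_len(n), group_tag = group, stringsAsFactors = FALSE))
}

# 12-bead PA chain topology: n_tail tail beads + the rest head beads,
# MARTINI-like bead mass 72 amu.
.pa_bead_topology <- function(n_pa, beads_per_pa = 12L, n_tail = 4L) {
  nb <- n_pa * beads_per_pa
  per <- rep(seq_len(n_pa), each = beads_per_pa)
  bead_in_pa <- rep(seq_len(beads_per_pa), n_pa)
  tag <- ifelse(bead_in_pa <= n_tail, "hydrophobic_tail", "hydrophilic_head")
  atoms <- data.frame(
    atom_id = seq_len(nb),
    name = paste0(ifelse(bead_in_pa <= n_tail, "T", "H"), bead_in_pa),
    element = "B", mass = 72, residue_name = "PA",
    residue_index = per, molecule_id = per, group_tag = tag,
    stringsAsFactors = FALSE)
  first <- (per - 1L) * 0L + seq_len(nb)
  bonds <- cbind(seq_len(nb - 1L), 2:nb)
  bonds <- bonds[bead_in_pa[bonds[, 1]] != beads_per_pa, , drop = FALSE]
  topology(atoms, bonds)
}

#' Generate an ideal-gas trajectory
#'
#' Single-site particles i.i.d. uniform in the box, independently each frame:
#' the null model with g(r) = 1 and full isotropy.
#'
#' @param n particle count (>= 2).
#' @param box box edges, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param dt frame spacing, ps.
#' @return a `trajectory` of water-tagged single sites.
#' @export
gen_ideal_gas <- function(n, box, n_frames = 1L, seed, dt = 1) {
  if (n < 2) stop("n must be >= 2")
  set.seed(seed)
  top <- .single_site_topology(n)
  frames <- lapply(seq_len(n_frames), function(i) {
    xyz <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                 stats::runif(n, 0, box[3]))
    new_frame(xyz, box, time = (i - 1) * dt)
  })
  trajectory(top, frames, dt = dt)
}

#' Generate an ideal lattice under periodic boundaries
#'
#' `fcc`: 12 nearest neighbours at `a/sqrt(2)`; `sc`: 6 at `a`;
#' `diamond_ice`: the diamond/cubic-ice site lattice with 4 nearest
#' neighbours at `a*sqrt(3)/4` forming ideal tetrahedral angles
#' `acos(-1/3)`.
#'
#' @param kind `"fcc"`, `"sc"`, or `"diamond_ice"`.
#' @param a cubic lattice constant, Angstrom.
#' @param repeats unit-cell repeats per axis (scalar or length 3, >= 2).
#' @return list with `topology` and `frame` (box = `a * repeats`).
#' @export
gen_lattice <- function(kind = c("fcc", "sc", "diamond_ice"), a, repeats) {
  kind <- match.arg(kind)
  repeats <- rep(as.integer(repeats), length.out = 3)
  if (any(repeats < 2)) stop("repeats must be >= 2 per axis")
  basis <- switch(kind,
    sc = matrix(c(0, 0, 0), ncol = 3, byrow = TRUE),
    fcc = matrix(c(0, 0, 0, 0.5, 0.5, 0, 0.5, 0, 0.5, 0, 0.5, 0.5),
                 ncol = 3, byrow = TRUE),
    diamond_ice = rbind(
      matrix(c(0, 0, 0, 0.5, 0.5, 0, 0.5, 0, 0.5, 0, 0.5, 0.5),
             ncol = 3, byrow = TRUE),
      matrix(c(0, 0, 0, 0.5, 0.5, 0, 0.5, 0, 0.5, 0, 0.5, 0.5),
             ncol = 3, byrow = TRUE) + 0.25))
  cells <- as.matrix(expand.grid(0:(repeats[1] - 1), 0:(repeats[2] - 1),
                                 0:(repeats[3] - 1)))
  xyz <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sweep(basis, 2, as.numeric(cells[i, ]), "+")
  })) * a
  top <- .single_site_topology(nrow(xyz))
  list(topology = top, frame = new_frame(xyz, a * repeats))
}

#' Generate hydration-shell fixtures around isolated sites
#'
#' Places `n_sites` hydrophilic sites on a cubic grid separated by at least
#' twice the outermost shell radius, then surrounds each with
#' `shell_counts[k]` water oxygens at radius `shell_radii[k]` plus Gaussian
#' radial jitter, directions uniform on the sphere. Defaults reproduce a
#' first hydration peak at 2.85 A (4 waters) and a second at 5.0 A
#' (12 waters).
#'
#' @param n_sites number of sites.
#' @param shell_radii shell radii, Angstrom.
#' @param shell_counts waters per shell.
#' @param jitter_sigma Gaussian radial jitter SD, Angstrom.
#' @param box box edges; `NULL` sizes a cube automatically.
#' @param seed RNG seed.
#' @return list with `topology` and `frame`; sites are tagged
#'   `hydrophilic_head`, shell particles `water`.
#' @export
gen_solvation_shell <- function(n_sites = 200L, shell_radii = c(2.85, 5.0),
                                shell_counts = c(4L, 12L), jitter_sigma = 0.05,
                                box = NULL, seed) {
  stopifnot(length(shell_radii) == length(shell_counts), all(shell_radii > 0))
  set.seed(seed)
  sep <- 2 * max(shell_radii) + 1
  per_axis <- ceiling(n_sites^(1 / 3))
  if (is.null(box)) box <- rep(per_axis * sep, 3)
  if (any(box < per_axis * sep)) {
    stop("box too small to separate ", n_sites, " sites by ", 2 * max(shell_radii), " A")
  }
  g <- as.matrix(expand.grid(seq_len(per_axis), seq_len(per_axis),
                             seq_len(per_axis)))[seq_len(n_sites), , drop = FALSE]
  sites <- sweep(g - 0.5, 2, box / per_axis, "*")
  waters <- list()
  for (k in seq_along(shell_radii)) {
    if (shell_counts[k] == 0L) next
    for (s in seq_len(n_sites)) {
      dirs <- sphere_sample(shell_counts[k])
      r <- shell_radii[k] + stats::rnorm(shell_counts[k], 0, jitter_sigma)
      waters[[length(waters) + 1L]] <- sweep(dirs * r, 2, sites[s, ], "+")
    }
  }
  wat <- do.call(rbind, waters)
  nw <- nrow(wat)
  atoms <- data.frame(
    atom_id = seq_len(n_sites + nw),
    name = c(rep("ST", n_sites), rep("O", nw)),
    element = c(rep("N", n_sites), rep("O", nw)),
    mass = c(rep(element_mass("N"), n_sites), rep(element_mass("O"), nw)),
    residue_name = c(rep("HEAD", n_sites), rep("HOH", nw)),
    residue_index = seq_len(n_sites + nw),
    molecule_id = seq_len(n_sites + nw),
    group_tag = c(rep("hydrophilic_head", n_sites), rep("water", nw)),
    stringsAsFactors = FALSE)
  list(topology = topology(atoms),
       frame = new_frame(wrap_coords(rbind(sites, wat), box), box))
}

# fibre centroid layout: vertices of a regular n-gon with side = spacing
# (every fibre's nearest neighbour is exactly one spacing away); n = 1 sits
# at the origin.
.fibre_centres <- function(n_fibres, spacing) {
  if (n_fibres == 1L) return(matrix(0, 1, 2))
  R <- spacing / (2 * sin(pi / n_fibres))
  th <- 2 * pi * (seq_len(n_fibres) - 1) / n_fibres
  cbind(R * cos(th), R * sin(th))
}

#' Generate a hexagonal bundle of periodic PA fibres
#'
#' Coarse-grained fixture emulating the assembled nanofibre architecture:
#' `n_fibres` z-aligned, box-periodic fibres of `pas_per_fibre` 12-bead PAs
#' each, with fibre centroids on a regular polygon of side
#' `centroid_spacing` (a hexagon for the default six fibres). Tail beads lie
#' within `0.5 * fibre_radius` of their fibre axis, head beads radially
#' outward to `fibre_radius`. PAs are stratified along z so each fibre is a
#' contiguous periodic aggregate; defaults give 300 PAs and
#' `50 / 4.55 nm ~ 11` PAs per nm of axis.
#'
#' @param n_fibres number of fibres (default 6).
#' @param pas_per_fibre PAs per fibre (default 50).
#' @param fibre_radius outer (head-bead) radius, Angstrom (default 25).
#' @param centroid_spacing nearest-neighbour centroid distance, Angstrom.
#' @param box_z axial box length, Angstrom (default 45.5).
#' @param seed RNG seed.
#' @param beads_per_pa,n_tail bead-chain layout (default 12 beads, 4 tail).
#' @param jitter per-bead Gaussian positional jitter SD, Angstrom.
#' @return list with `topology` and `frame`.
#' @export
gen_pa_bundle <- function(n_fibres = 6L, pas_per_fibre = 50L,
                          fibre_radius = 25, centroid_spacing = 50,
                          box_z = 45.5, seed, beads_per_pa = 12L,
                          n_tail = 4L, jitter = 0.25) {
  if (n_fibres > 1L && centroid_spacing < 2 * 0.5 * fibre_radius) {
    stop("fibre overlap: centroid_spacing < fibre core diameter")
  }
  set.seed(seed)
  centres <- .fibre_centres(n_fibres, centroid_spacing)
  R <- max(sqrt(rowSums(centres^2)))
  box_xy <- 2 * R + 4 * fibre_radius
  box <- c(box_xy, box_xy, box_z)
  centres <- sweep(centres, 2, box_xy / 2, "+")
  n_pa <- n_fibres * pas_per_fibre
  top <- .pa_bead_topology(n_pa, beads_per_pa, n_tail)
  radii <- c(seq(0.08, 0.48, length.out = n_tail),
             seq(0.55, 1.0, length.out = beads_per_pa - n_tail)) * fibre_radius
  xyz <- matrix(0, n_pa * beads_per_pa, 3)
  row <- 1L
  for (f in seq_len(n_fibres)) {
    zs <- (seq_len(pas_per_fibre) - 0.5 +
             stats::runif(pas_per_fibre, -0.4, 0.4)) * box_z / pas_per_fibre
    # helical golden-angle azimuth progression along z: cylindrically uniform
    # wall coverage with no azimuth/height correlation
    phis <- 2 * pi * ((seq_len(pas_per_fibre) * 0.3819660113 +
                         stats::runif(1)) %% 1) +
      stats::runif(pas_per_fibre, -0.15, 0.15)
    for (p in seq_len(pas_per_fibre)) {
      dir <- c(cos(phis[p]), sin(phis[p]))
      for (bidx in seq_len(beads_per_pa)) {
        xyz[row, ] <- c(centres[f, ] + radii[bidx] * dir, zs[p]) +
          stats::rnorm(3, 0, jitter)
        row <- row + 1L
      }
    }
  }
  list(topology = top, frame = new_frame(wrap_coords(xyz, box), box))
}

#' Generate a spherical PA micelle
#'
#' PAs arranged radially on a sphere with tails pointing inward, the product
#' of the hydrophobic-collapse stage.
#'
#' @param n_pa number of PAs.
#' @param radius outer (head-bead) radius, Angstrom.
#' @param seed RNG seed.
#' @param beads_per_pa,n_tail bead-chain layout.
#' @param box box edges; `NULL` gives a cube of edge `4 * radius`.
#' @return list with `topology` and `frame`.
#' @export
gen_micelle <- function(n_pa, radius, seed, beads_per_pa = 12L, n_tail = 4L,
                        box = NULL) {
  set.seed(seed)
  if (is.null(box)) box <- rep(4 * radius, 3)
  top <- .pa_bead_topology(n_pa, beads_per_pa, n_tail)
  dirs <- sphere_sample(n_pa)
  radii <- c(seq(0.08, 0.45, length.out = n_tail),
             seq(0.55, 1.0, length.out = beads_per_pa - n_tail)) * radius
  xyz <- matrix(0, n_pa * beads_per_pa, 3)
  row <- 1L
  for (p in seq_len(n_pa)) {
    for (bidx in seq_len(beads_per_pa)) {
      xyz[row, ] <- box / 2 + radii[bidx] * dirs[p, ]
      row <- row + 1L
    }
  }
  list(topology = top, frame = new_frame(wrap_coords(xyz, box), box))
}

#' Generate a harmonic-oscillator velocity trajectory
#'
#' Per atom and Cartesian component, the velocity is a sum of cosine modes
#' `A cos(2 pi c nu t + phi)` with independent random phases; positions are
#' the exact integrals. The closed-form VACF is `cos(2 pi c nu tau)`
#' (averaged over phases), giving an analytic oracle for the vibrational
#' density of states.
#'
#' @param freq mode wavenumbers, cm^-1 (0 means a constant-velocity mode).
#' @param n_atoms number of atoms.
#' @param n_steps number of stored frames.
#' @param dt_fs frame spacing, femtoseconds.
#' @param seed RNG seed.
#' @param amplitude velocity amplitude per mode, Angstrom/ps.
#' @return a `trajectory` with velocities (dt stored in ps).
#' @export
gen_harmonic_velocity_traj <- function(freq, n_atoms, n_steps, dt_fs = 1,
                                       seed, amplitude = 1) {
  set.seed(seed)
  top <- .single_site_topology(n_atoms)
  box <- rep(1e4, 3)
  dt_ps <- dt_fs * 1e-3
  t_ps <- (seq_len(n_steps) - 1) * dt_ps
  omega <- 2 * pi * hf_constants$c_cm_s * freq * 1e-12  # rad/ps
  vel <- array(0, c(n_steps, n_atoms, 3))
  pos <- array(0, c(n_steps, n_atoms, 3))
  base <- box / 2
  for (m in seq_along(omega)) {
    for (k in 1:3) {
      phi <- stats::runif(n_atoms, 0, 2 * pi)
      ph <- outer(t_ps, rep(1, n_atoms)) * omega[m] +
        outer(rep(1, n_steps), phi)
      vel[, , k] <- vel[, , k] + amplitude * cos(ph)
      pos[, , k] <- pos[, , k] + if (omega[m] > 0) {
        amplitude / omega[m] * (sin(ph) - sin(outer(rep(1, n_steps), phi)))
      } else {
        amplitude * outer(t_ps, cos(phi))
      }
    }
  }
  frames <- lapply(seq_len(n_steps), function(i) {
    xi <- matrix(pos[i, , ], ncol = 3)
    new_frame(sweep(xi, 2, base, "+"), box,
              time = t_ps[i], velocities = matrix(vel[i, , ], ncol = 3))
  })
  trajectory(top, frames, dt = dt_ps)
}
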