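# Water-structure metrics against brute-force oracles and closed forms.

test_that("the RDF is flat for an ideal gas and conserves pair counts", {
  ig <- gen_ideal_gas(1000, c(30, 30, 30), n_frames = 20, seed = 5)
  r <- compute_rdf(ig, "all", "all", r_max = 10, dr = 0.25)
  keep <- r$r >= 2
  expect_true(all(abs(r$g[keep] - 1) < 0.1))
  # pair-count bookkeeping: histogram total equals accumulated pairs < r_max
  d <- min_image_dist(ig$frames[[1]]$coords, ig$frames[[1]]$coords,
                      ig$frames[[1]]$box)
  one <- trajectory(ig$topology, ig$frames[1])
  r1 <- compute_rdf(one, "all", "all", r_max = 10, dr = 0.25)
  expect_equal(sum(r1$pair_counts), sum(d < 10) - 1000)
})

test_that("a single fixed pair lands in exactly one bin", {
  top <- topology(data.frame(atom_id = 1:2, name = "O", element = "O",
                             mass = 16, residue_name = "HOH",
                             residue_index = 1:2, molecule_id = 1:2,
                             group_tag = "water"))
  fr <- new_frame(rbind(c(5, 5, 5), c(10, 5, 5)), c(30, 30, 30))
  r <- compute_rdf(list(topology = top, frame = fr), 1L, 2L, r_max = 8,
                   dr = 0.1)
  nz <- which(r$pair_counts > 0)
  expect_length(nz, 1L)
  expect_true(r$bin_edges[nz] <= 5 && r$bin_edges[nz + 1] >= 5)
  expect_error(compute_rdf(list(topology = top, frame = fr), 1L, 2L,
                           r_max = 20, dr = 0.1), "minimum-image")
})

test_that("hydration-shell peaks recover the generator radii", {
  for (r0 in c(2.5, 2.85, 3.5)) {
    sh <- gen_solvation_shell(n_sites = 64, shell_radii = r0,
                              shell_counts = 6, jitter_sigma = 0.05, seed = 3)
    rdf <- compute_rdf(sh, "group hydrophilic_head", "group water",
                       r_max = 8, dr = 0.05)
    expect_equal(rdf_first_peak(rdf), r0, tolerance = 0.06)
  }
})

test_that("q6 matches the addition-theorem oracle on small configurations", {
  # perfect lattices: implementation (spherical-harmonic sums) vs the
  # independent Legendre-P6 oracle
  fcc <- gen_lattice("fcc", a = 4, repeats = 2)
  got <- compute_q6(fcc, "all", neighbours = list(cutoff = 3.2))
  want <- oracle_q6_mean(fcc$frame$coords, fcc$frame$box, 3.2)
  expect_equal(got$values, want, tolerance = 1e-8)
  expect_equal(got$values, 0.57452, tolerance = 1e-4)

  sc <- gen_lattice("sc", a = 4, repeats = 2)
  got_sc <- compute_q6(sc, "all", neighbours = list(cutoff = 4.1))
  expect_equal(got_sc$values, oracle_q6_mean(sc$frame$coords, sc$frame$box,
                                             4.1),
               tolerance = 1e-8)

  # jittered configuration, both paths on identical neighbour sets
  set.seed(21)
  co <- gen_lattice("fcc", a = 4, repeats = 2)$frame$coords +
    matrix(rnorm(3 * 32, 0, 0.15), ncol = 3)
  box <- c(8, 8, 8)
  lst <- list(topology = hydrafibre:::.single_site_topology(32),
              frame = new_frame(wrap_coords(co, box), box))
  got_j <- compute_q6(lst, "all", neighbours = list(cutoff = 3.2))
  expect_equal(got_j$values, oracle_q6_mean(wrap_coords(co, box), box, 3.2),
               tolerance = 1e-8)

  # isotropy annihilates the average: many uniform directions
  set.seed(4)
  expect_lt(oracle_q6_from_dirs(sphere_sample(512)), 0.1)
})

test_that("q6 is invariant under box-compatible rotation", {
  fcc <- gen_lattice("fcc", a = 4, repeats = 3)
  q1 <- compute_q6(fcc, "all", neighbours = list(cutoff = 3.2))$values
  # 90-degree rotation about z maps the cubic box onto itself
  co <- fcc$frame$coords
  rot <- cbind(co[, 2], fcc$frame$box[1] - co[, 1], co[, 3])
  fr <- new_frame(wrap_coords(rot, fcc$frame$box), fcc$frame$box)
  q2 <- compute_q6(list(topology = fcc$topology, frame = fr), "all",
                   neighbours = list(cutoff = 3.2))$values
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("tetrahedral order: ice lattice exactly 1, degenerate and random", {
  ice <- gen_lattice("diamond_ice", a = 4, repeats = 2)
  q <- compute_tetrahedral_order(ice, "all")
  expect_equal(q$values, 1, tolerance = 1e-10)

  # all four neighbours collinear in the same direction: every pair cosine
  # is 1 and the defining sum gives 1 - (3/8)*6*(4/3)^2 = -3
  expect_equal(oracle_qtet_from_dirs(matrix(rep(c(1, 0, 0), 4), 4, 3,
                                            byrow = TRUE)), -3)
  co <- rbind(c(10, 10, 10), c(12, 10, 10), c(13, 10, 10), c(14, 10, 10),
              c(15, 10, 10))
  lst <- list(topology = hydrafibre:::.single_site_topology(5),
              frame = new_frame(co, c(40, 40, 40)))
  got <- compute_tetrahedral_order(lst, 1L, pool = "all")
  expect_equal(got$values, -3, tolerance = 1e-10)

  # uniformly random directions: mean of the defining sum is 0
  set.seed(6)
  vals <- replicate(3000, oracle_qtet_from_dirs(sphere_sample(4)))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)

  # implementation vs oracle on a disordered configuration
  ig <- gen_ideal_gas(120, c(12, 12, 12), n_frames = 1, seed = 31)
  got2 <- compute_tetrahedral_order(ig, "all")
  expect_equal(got2$values, oracle_qtet_mean(ig$frames[[1]]$coords,
                                             ig$frames[[1]]$box),
               tolerance = 1e-8)
})

test_that("translational order separates gas, jittered and crystal", {
  ig <- gen_ideal_gas(600, c(20, 20, 20), n_frames = 4, seed = 12)
  t_gas <- compute_translational_order(ig, "all")
  # the rectified integrand has a finite-sampling noise floor; the gas value
  # must sit far below every ordered configuration
  expect_lt(mean(t_gas$values), 0.25)
  lat <- gen_lattice("sc", a = 3, repeats = 6)
  t_lat <- compute_translational_order(lat, "all")
  expect_gt(t_lat$values, 1)
  # monotone in disorder
  tv <- vapply(c(0.05, 0.2, 0.5), function(j) {
    set.seed(40)
    co <- lat$frame$coords + matrix(rnorm(3 * n_atoms(lat$topology), 0, j),
                                    ncol = 3)
    fr <- new_frame(wrap_coords(co, lat$frame$box), lat$frame$box)
    compute_translational_order(list(topology = lat$topology, frame = fr),
                                "all")$values
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
})

test_that("ordering metrics fall monotonically with shell jitter", {
  qv <- vapply(c(0.05, 0.2, 0.5), function(j) {
    sh <- gen_solvation_shell(n_sites = 27, shell_radii = 2.85,
                              shell_counts = 6, jitter_sigma = j, seed = 17)
    compute_q6(sh, "group water", neighbours = list(k_nearest = 5))$values
  }, numeric(1))
  expect_true(all(diff(qv) < 0))
})

test_that("hydrogen bonds follow the geometric criterion", {
  # linear dimer: donor O-H pointing at the acceptor O at 2.85 A
  w <- make_waters(rbind(c(10, 10, 10), c(12.85, 10, 10)))
  hb <- find_hbonds(w$frame, w$topology, "element O", "element O")
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.85, tolerance = 1e-9)

  # rotate the donor so the H-D-A angle exceeds the cutoff by 5 degrees
  th <- (30 + 5) * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  co <- w$frame$coords
  co[2:3, ] <- sweep(sweep(co[2:3, ], 2, co[1, ]) %*% t(rot), 2, co[1, ], "+")
  fr <- new_frame(co, w$frame$box)
  hb2 <- find_hbonds(fr, w$topology, "element O", "element O")
  expect_equal(nrow(hb2), 0L)

  # brute-force triple-loop equality on a 50-water configuration
  set.seed(23)
  opos <- matrix(runif(150, 0, 15), 50, 3)
  sys <- make_waters(opos, box = c(15, 15, 15), rotate = TRUE)
  hb3 <- find_hbonds(sys$frame, sys$topology, "element O", "element O")
  don <- which(sys$topology$atoms$element == "O")
  expect_equal(nrow(hb3),
               oracle_hbond_count(sys$frame, sys$topology, don, don, 3.5, 30))

  # donors without hydrogens are an error
  bare <- gen_ideal_gas(5, c(20, 20, 20), seed = 2)
  expect_error(find_hbonds(bare$frames[[1]], bare$topology, "all", "all"),
               "without bonded hydrogens")
})

test_that("density profiles integrate to the selected mass", {
  fr <- new_frame(matrix(c(15, 15, 15), 1, 3), c(30, 30, 30))
  top <- hydrafibre:::.single_site_topology(1, element = "N",
                                            residue = "HEAD", group = "other")
  solv <- reinsert_water(fr, top, overall_density = 1.0, seed = 14)
  prof <- compute_density_profile(list(topology = solv$topology,
                                       frame = solv$frame),
                                  "group water", "x", dr = 5)
  expect_true(all(abs(prof$density - 1) < 0.05))
  # mass conservation: sum(rho * slab volume) = selected mass
  ids <- select_atoms(solv$topology, solv$frame, "group water")
  mass_g <- sum(solv$topology$atoms$mass[ids]) * hf_constants$amu_g
  slab_cc <- 5 * 30 * 30 * 1e-24
  expect_equal(sum(prof$density) * slab_cc, mass_g, tolerance = 1e-9)
  # vacuum slab: zero bins
  fr2 <- new_frame(rbind(c(2, 5, 5)), c(30, 10, 10))
  top2 <- hydrafibre:::.single_site_topology(1)
  prof2 <- compute_density_profile(list(topology = top2, frame = fr2), "all",
                                   "x", dr = 5)
  expect_equal(sum(prof2$density > 0), 1L)
})

test_that("radial bead distributions are concentrated and conserved", {
  bun <- gen_pa_bundle(n_fibres = 1, pas_per_fibre = 30, seed = 19)
  cen <- c(bun$frame$box[1:2] / 2, 0)
  rn <- radial_number_distribution(bun, cen, c(0, 0, 1),
                                   list(tail = "group hydrophobic_tail",
                                        head = "group hydrophilic_head"),
                                   dr = 2)
  expect_equal(sum(rn$tail), 30 * 4)
  expect_equal(sum(rn$head), 30 * 8)
  expect_true(all(rn$tail[rn$r > 15] == 0))
  expect_gt(sum(rn$tail[rn$r < 15]), 0.99 * sum(rn$tail))
  # a cylinder of waters occupies a single annulus
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  wat <- make_waters(cbind(30 + 20.3 * cos(th), 30 + 20.3 * sin(th), 10),
                     box = c(60, 60, 20))
  rw <- radial_number_distribution(wat, c(30, 30, 0), c(0, 0, 1),
                                   list(w = "element O"), dr = 1)
  expect_equal(sum(rw$w > 0), 1L)
  expect_equal(rw$r[which(rw$w > 0)], 20.5)
})
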