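# Aggregate census, conformation and chirality analyses.

test_that("end-to-end distances unwrap across periodic boundaries", {
  top <- hydrafibre:::.pa_bead_topology(1)
  xyz <- cbind(seq(0, 22, by = 2), 0, 0) + 30
  tr <- trajectory(top, list(new_frame(xyz, rep(100, 3))))
  e <- end_to_end(tr, c("T1", "H12"))
  expect_equal(e$mean, 22)
  expect_equal(e$sd, NA_real_, ignore_attr = TRUE)

  # folded chain is shorter than the straight one
  fold <- xyz
  fold[7:12, 1] <- fold[6, 1] - seq(2, 12, by = 2)
  trf <- trajectory(top, list(new_frame(fold, rep(100, 3))))
  expect_lt(end_to_end(trf, c("T1", "H12"))$mean, 22)

  # chain crossing the boundary equals its whole-box translate
  box <- c(40, 40, 40)
  crossing <- cbind(seq(30, 52, by = 2) %% 40, 5, 5)
  trc <- trajectory(top, list(new_frame(crossing, box)))
  centred <- cbind(seq(5, 27, by = 2), 5, 5)
  trn <- trajectory(top, list(new_frame(centred, box)))
  expect_equal(end_to_end(trc, c("T1", "H12"))$mean,
               end_to_end(trn, c("T1", "H12"))$mean, tolerance = 1e-10)
  expect_error(end_to_end(tr, c("T1", "NOPE")), "missing endpoint")
})

test_that("single-linkage clustering is exact at the contact boundary", {
  top <- hydrafibre:::.pa_bead_topology(2)
  place <- function(gap) {
    a <- cbind(seq(0, 22, by = 2), 0, 0) + 10
    b <- a; b[, 2] <- b[, 2] + gap
    new_frame(rbind(a, b), rep(60, 3))
  }
  eps <- 1e-6
  cl_in <- cluster_molecules(place(6 - eps), top, "group hydrophobic_tail", 6)
  expect_equal(length(cl_in$sizes), 1L)
  cl_out <- cluster_molecules(place(6 + eps), top, "group hydrophobic_tail", 6)
  expect_equal(length(cl_out$sizes), 2L)
})

test_that("clustering agrees with the exhaustive union-find oracle", {
  # random beads scattered so clusters of several molecules form
  set.seed(33)
  n_mol <- 40
  mol <- rep(seq_len(n_mol), each = 2)
  atoms <- data.frame(atom_id = seq_len(2 * n_mol), name = "T1",
                      element = "B", mass = 72, residue_name = "PA",
                      residue_index = mol, molecule_id = mol,
                      group_tag = "hydrophobic_tail")
  top <- topology(atoms)
  box <- c(30, 30, 30)
  base <- matrix(runif(3 * n_mol, 0, 30), n_mol, 3)
  co <- base[rep(seq_len(n_mol), each = 2), ] +
    matrix(rnorm(6 * n_mol, 0, 1.5), 2 * n_mol, 3)
  fr <- new_frame(wrap_coords(co, box), box)
  got <- cluster_molecules(fr, top, "group hydrophobic_tail", 5)
  expect_equal(sort(got$sizes, decreasing = TRUE),
               oracle_cluster_sizes(fr$coords, mol, box, 5))
  expect_equal(sum(got$sizes), n_mol)

  # bundle fixture: the printed architecture (six aggregates of ~50)
  bun <- gen_pa_bundle(seed = 42)
  cl <- cluster_molecules(bun$frame, bun$topology, "group hydrophobic_tail", 6)
  expect_equal(cl$sizes, rep(50, 6))
})

test_that("cluster labels and metrics are invariant under box translation", {
  bun <- gen_pa_bundle(n_fibres = 2, pas_per_fibre = 15, seed = 21)
  cl1 <- cluster_molecules(bun$frame, bun$topology, "group hydrophobic_tail", 6)
  shift <- c(13.7, -8.1, 22.9)
  fr2 <- new_frame(wrap_coords(sweep(bun$frame$coords, 2, -shift), bun$frame$box),
                   bun$frame$box)
  cl2 <- cluster_molecules(fr2, bun$topology, "group hydrophobic_tail", 6)
  expect_equal(cl1$sizes, cl2$sizes)
  expect_equal(cl1$molecules$cluster, cl2$molecules$cluster)
  f1 <- fibre_metrics(cl1, 1, bun$frame, bun$topology)
  f2 <- fibre_metrics(cl2, 1, fr2, bun$topology)
  expect_equal(f1$linear_density, f2$linear_density, tolerance = 1e-9)
  expect_equal(f1$diameter, f2$diameter, tolerance = 1e-6)
})

test_that("aggregates classify as micelle or periodic-spanning fibre", {
  mic <- gen_micelle(50, 20, seed = 4)
  clm <- cluster_molecules(mic$frame, mic$topology, "group hydrophobic_tail", 6)
  cm <- classify_aggregate(clm, 1, mic$frame, mic$topology)
  expect_identical(cm$class, "micelle")
  expect_equal(cm$axial_extent, 2 * 20, tolerance = 0.2 * 40)

  fib <- gen_pa_bundle(n_fibres = 1, seed = 5)
  clf <- cluster_molecules(fib$frame, fib$topology, "group hydrophobic_tail", 6)
  cf <- classify_aggregate(clf, 1, fib$frame, fib$topology)
  expect_identical(cf$class, "fibre")
  expect_lt(acos(abs(cf$axis[3])) * 180 / pi, 5)
  # radius: RMS radial distance of the tail beads about the axis; the
  # construction places tails at fixed fractions of the fibre radius
  want_rms <- sqrt(mean((c(seq(0.08, 0.48, length.out = 4)) * 25)^2))
  expect_equal(cf$radius, want_rms, tolerance = 0.1)
  expect_lt(cf$radius, 0.5 * 25)
})

test_that("fibre metrics recover the construction numbers", {
  fib <- gen_pa_bundle(n_fibres = 1, seed = 5)
  cl <- cluster_molecules(fib$frame, fib$topology, "group hydrophobic_tail", 6)
  fm <- fibre_metrics(cl, 1, fib$frame, fib$topology)
  expect_equal(fm$linear_density, 50 / 4.55, tolerance = 1e-9)
  # doubling the axial box at fixed PA count halves the linear density
  fib2 <- gen_pa_bundle(n_fibres = 1, box_z = 91, seed = 5)
  cl2 <- cluster_molecules(fib2$frame, fib2$topology, "group hydrophobic_tail", 6)
  fm2 <- fibre_metrics(cl2, 1, fib2$frame, fib2$topology)
  expect_equal(fm2$linear_density, fm$linear_density / 2, tolerance = 1e-9)
  # diameter ~ twice the 95th percentile of the constructed radii
  radii <- c(seq(0.08, 0.48, length.out = 4), seq(0.55, 1, length.out = 8)) * 25
  expect_equal(fm$diameter, 2 * as.numeric(quantile(radii, 0.95)),
               tolerance = 0.1)
  expect_error(fibre_metrics(
    cluster_molecules(gen_micelle(20, 15, seed = 2)$frame,
                      gen_micelle(20, 15, seed = 2)$topology,
                      "group hydrophobic_tail", 6),
    1, gen_micelle(20, 15, seed = 2)$frame,
    gen_micelle(20, 15, seed = 2)$topology), "micelle")
})

test_that("lattice spacing recovers the generator layout", {
  for (sp in c(40, 50, 60)) {
    bun <- gen_pa_bundle(centroid_spacing = sp, seed = 7)
    cl <- cluster_molecules(bun$frame, bun$topology, "group hydrophobic_tail", 6)
    cents <- t(vapply(seq_along(cl$sizes), function(i) {
      classify_aggregate(cl, i, bun$frame, bun$topology)$centroid
    }, numeric(3)))
    ls <- lattice_spacing(cents, bun$frame$box)
    expect_equal(ls$mean_spacing, sp, tolerance = 0.5 / 50)
    # hexagon-ring layout: every fibre has exactly two nearest neighbours
    expect_equal(ls$coordination, rep(2, 6), ignore_attr = TRUE)
  }
  expect_error(lattice_spacing(matrix(1, 1, 3), c(10, 10, 10)), "at least 2")
})

test_that("census bookkeeping over a fission event conserves molecules", {
  bun <- gen_pa_bundle(n_fibres = 2, pas_per_fibre = 50, seed = 31)
  cl0 <- cluster_molecules(bun$frame, bun$topology, "group hydrophobic_tail", 6)
  expect_equal(cl0$sizes, c(50, 50))
  # split fibre 1 into two children of ~25 PAs by pulling apart half its
  # molecules along x
  fib1 <- cl0$molecules$molecule_id[cl0$molecules$cluster == 1]
  movers <- fib1[1:25]
  co <- bun$frame$coords
  rows <- bun$topology$atoms$molecule_id %in% movers
  co[rows, 1] <- co[rows, 1] + 60
  fr <- new_frame(wrap_coords(co, bun$frame$box), bun$frame$box)
  cl1 <- cluster_molecules(fr, bun$topology, "group hydrophobic_tail", 6)
  expect_equal(sum(cl1$sizes), 100)
  expect_equal(sort(cl1$sizes), c(25, 25, 50))
})

test_that("dihedrals, Ramachandran regions and chirality are exact", {
  # planar references: cis = 0, trans = 180
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)),
               0)
  expect_equal(abs(dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                  c(1, 0, 0))), 180)
  # sign flips under mirror reflection
  a <- c(1, 1, 0.3); b <- c(0, 1, 0); cc <- c(0, 0, 0); d <- c(1, 0, 0.4)
  mir <- function(p) c(p[1], p[2], -p[3])
  expect_equal(dihedral_angle(mir(a), mir(b), mir(cc), mir(d)),
               -dihedral_angle(a, b, cc, d))

  # internal-coordinate construction at the polyproline-II centre
  bb <- build_backbone(-65, 145, n_res = 5)
  rs <- ramachandran(bb)
  expect_equal(rs$phi, rep(-65, nrow(rs)), tolerance = 1e-6)
  expect_equal(rs$psi, rep(145, nrow(rs)), tolerance = 1e-6)
  expect_true(all(rs$region == "P_II"))
  expect_true(all(rs$chirality == "L"))

  # mirrored coordinates invert the chirality label
  mfr <- bb$frame
  mfr$coords[, 3] <- -mfr$coords[, 3] + 100
  rs_m <- ramachandran(list(topology = bb$topology, frame = mfr))
  expect_true(all(rs_m$chirality == "D"))
  expect_equal(rs_m$phi, rep(65, nrow(rs_m)), tolerance = 1e-6)

  # the ideal L-alanine template anchors the convention
  tmpl <- l_alanine_template()
  expect_identical(chirality(tmpl["N", ], tmpl["CA", ], tmpl["C", ],
                             tmpl["CB", ]), "L")
  expect_identical(chirality(mir(tmpl["N", ]), mir(tmpl["CA", ]),
                             mir(tmpl["C", ]), mir(tmpl["CB", ])), "D")
})
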