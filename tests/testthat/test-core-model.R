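# Core types, file round trips, periodic geometry, and the selection
# language.

test_that("topology and frame invariants are enforced", {
  atoms <- data.frame(atom_id = 1:2, name = "O", element = "O",
                      mass = c(16, -1), residue_name = "HOH",
                      residue_index = 1:2, molecule_id = 1:2,
                      group_tag = "water")
  expect_error(topology(atoms), "masses")
  atoms$mass <- 16
  atoms$atom_id <- c(1L, 3L)
  expect_error(topology(atoms), "dense")
  atoms$atom_id <- 1:2
  expect_error(topology(atoms, rbind(c(1, 5))), "non-existent")
  expect_error(new_frame(matrix(c(0, 0, Inf), 1, 3), c(10, 10, 10)), "finite")
  expect_error(new_frame(matrix(0, 1, 3), c(10, 0, 10)), "box")
  top <- topology(atoms)
  f1 <- new_frame(matrix(0, 2, 3), c(10, 10, 10), time = 0)
  f2 <- new_frame(matrix(1, 2, 3), c(10, 10, 10), time = 0)
  expect_error(trajectory(top, list(f1, f2)), "increasing")
})

test_that("structure files round-trip to format precision", {
  sys <- gen_micelle(4, 12, seed = 2)
  for (fmt in c("pdb", "gro", "xyz")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_structure(sys$topology, sys$frame, f, fmt)
    rt <- read_structure(f, fmt)
    tol <- switch(fmt, pdb = 1e-3, gro = 6e-3, xyz = 1e-5)
    expect_lt(max(abs(rt$frame$coords - sys$frame$coords)), tol)
    expect_equal(rt$frame$box, sys$frame$box, tolerance = 1e-6)
    expect_equal(n_atoms(rt$topology), n_atoms(sys$topology))
  }
})

test_that("a minimal water PDB parses with box and grouping", {
  f <- tempfile(fileext = ".pdb")
  rec <- function(id, nm, el, x, y, z) {
    sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            id, nm, "HOH", 1L, x, y, z, el)
  }
  writeLines(c(
    "CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1           1",
    rec(1, "OW", "O", 10, 10, 10),
    rec(2, "HW1", "H", 10.957, 10, 10),
    rec(3, "HW2", "H", 9.76, 10.926, 10),
    "END"), f)
  st <- read_structure(f, "pdb")
  expect_equal(n_atoms(st$topology), 3L)
  expect_equal(length(unique(st$topology$atoms$molecule_id)), 1L)
  expect_equal(st$frame$box, c(30, 30, 30))
  expect_true(all(st$topology$atoms$group_tag == "water"))
})

test_that("triclinic and malformed inputs raise explicit errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   30.000   30.000   30.000  90.00  95.00  90.00 P 1           1",
    "ATOM      1  OW   HOH     1      10.000  10.000  10.000  1.00  0.00           O"),
    f)
  expect_error(read_structure(f, "pdb"), "triclinic")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  OW   HOH     1      10.000  xx.000  10.000  1.00  0.00           O"),
    f2)
  expect_error(read_structure(f2, "pdb"), "line 2")
  f3 <- tempfile(fileext = ".xyz")
  writeLines(c("1", "no box here", "O 1.0 1.0 1.0"), f3)
  expect_error(read_structure(f3, "xyz"), "box")
})

test_that("GRO files parse residues, masses and nm units", {
  f <- tempfile(fileext = ".gro")
  writeLines(c(
    "two residues", "    5",
    "    1HOH    OW     1   1.000   1.000   1.000",
    "    1HOH   HW1     2   1.096   1.000   1.000",
    "    1HOH   HW2     3   0.976   1.093   1.000",
    "    2LYS    NZ     4   2.000   2.000   2.000",
    "    2LYS    CA     5   2.100   2.000   2.000",
    "   3.00000   3.00000   3.00000"), f)
  st <- read_structure(f, "gro")
  expect_equal(unique(st$topology$atoms$molecule_id), c(1L, 2L))
  expect_equal(st$frame$box, c(30, 30, 30))
  expect_equal(st$frame$coords[1, ], c(10, 10, 10))
  expect_equal(st$topology$atoms$mass[4], element_mass("N"))
  expect_equal(st$topology$atoms$group_tag[4:5], rep("hydrophilic_head", 2))
})

test_that("trajectory streams round-trip (XYZ-multi and DCD)", {
  ig <- gen_ideal_gas(40, c(20, 25, 30), n_frames = 10, seed = 8)
  fx <- tempfile(fileext = ".xyz")
  write_trajectory(ig, fx, "xyz")
  rx <- read_trajectory(fx, ig$topology, "xyz")
  expect_equal(n_frames(rx), 10L)
  expect_equal(rx$dt, ig$dt)
  expect_lt(max(abs(rx$frames[[10]]$coords - ig$frames[[10]]$coords)), 1e-5)

  fd <- tempfile(fileext = ".dcd")
  write_trajectory(ig, fd, "dcd")
  rd <- read_trajectory(fd, ig$topology, "dcd")
  expect_equal(n_frames(rd), 10L)
  expect_lt(max(abs(rd$frames[[7]]$coords - ig$frames[[7]]$coords)), 1e-4)
  expect_equal(rd$frames[[1]]$box, c(20, 25, 30), tolerance = 1e-6)

  expect_error(
    read_trajectory(fd, gen_ideal_gas(7, c(10, 10, 10), seed = 1)$topology,
                    "dcd"),
    "frame 0")
})

test_that("velocity streams attach to every frame", {
  hv <- gen_harmonic_velocity_traj(800, 3, 32, 1, seed = 4)
  fc <- tempfile(fileext = ".xyz"); fv <- tempfile(fileext = ".xyz")
  write_trajectory(hv, fc, "xyz", velocity_path = fv)
  rt <- read_trajectory(fc, hv$topology, "xyz", velocity_paths = fv)
  expect_false(is.null(rt$frames[[32]]$velocities))
  expect_lt(max(abs(rt$frames[[17]]$velocities - hv$frames[[17]]$velocities)),
            1e-6)
})

test_that("minimum-image displacement matches 27-image enumeration", {
  expect_equal(
    sqrt(sum(minimum_image_displacement(c(1, 0, 0), c(29, 0, 0),
                                        c(30, 30, 30))^2)), 2)
  expect_equal(minimum_image_displacement(c(3, 4, 5), c(3, 4, 5),
                                          c(30, 30, 30)), c(0, 0, 0))
  set.seed(11)
  box <- c(17, 23, 31)
  for (i in 1:1000) {
    a <- runif(3) * box; b <- runif(3) * box
    d <- minimum_image_displacement(a, b, box)
    expect_true(all(d > -box / 2 - 1e-12 & d <= box / 2 + 1e-12))
    expect_lt(abs(sqrt(sum(d^2)) - oracle_min_image_dist(a, b, box)), 1e-10)
  }
})

test_that("selection grammar is deterministic, molecule-completing, monotone", {
  w <- make_waters(rbind(c(14.9, 10, 10), c(25.1, 10, 10)))
  ha <- data.frame(atom_id = 7L, name = "NZ", element = "N",
                   mass = element_mass("N"), residue_name = "LYS",
                   residue_index = 3L, molecule_id = 3L,
                   group_tag = "hydrophilic_head")
  top <- topology(rbind(w$topology$atoms, ha), w$topology$bonds)
  fr <- new_frame(rbind(w$frame$coords, c(10, 10, 10)), c(50, 50, 50))

  expect_equal(select_atoms(top, fr, "group water"), 1:6)
  # boundary straddle: O at 4.9 A selects the whole first water, O at 5.1
  # selects nothing of the second
  expect_equal(select_atoms(top, fr,
                            "group water within 5.0 of group hydrophilic_head"),
               1:3)
  # idempotence and monotonicity in the shell radius
  s5 <- select_atoms(top, fr, "group water within 5.0 of group hydrophilic_head")
  expect_equal(select_atoms(top, fr,
                            "group water within 5.0 of group hydrophilic_head"),
               s5)
  for (r in c(6, 9, 16)) {
    sr <- select_atoms(top, fr, sprintf(
      "group water within %.1f of group hydrophilic_head", r))
    expect_true(all(s5 %in% sr))
    s5 <- sr
  }
  expect_equal(select_atoms(top, fr, "element O and resname HOH"), c(1L, 4L))
  expect_equal(select_atoms(top, fr, "not group water"), 7L)
  expect_error(select_atoms(top, fr, "group water withn 5"), "position")
  expect_error(select_atoms(top, fr, "within 5 of"), "position|end")
})

test_that("shells around a synthetic fibre exclude the core", {
  bun <- gen_pa_bundle(n_fibres = 1, pas_per_fibre = 20, seed = 3)
  # add a ring of water beads outside the fibre surface
  nb <- n_atoms(bun$topology)
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- cbind(bun$frame$box[1] / 2 + 30 * cos(th),
                bun$frame$box[2] / 2 + 30 * sin(th), bun$frame$box[3] / 2)
  watoms <- data.frame(atom_id = nb + seq_len(24), name = "W", element = "O",
                       mass = 72, residue_name = "W",
                       residue_index = nb + seq_len(24),
                       molecule_id = max(bun$topology$atoms$molecule_id) +
                         seq_len(24),
                       group_tag = "water")
  top <- topology(rbind(bun$topology$atoms, watoms), bun$topology$bonds)
  fr <- new_frame(rbind(bun$frame$coords, ring), bun$frame$box)
  sel <- select_atoms(top, fr, "group water within 15.0 of group hydrophilic_head")
  expect_gt(length(sel), 0)
  expect_true(all(top$atoms$group_tag[sel] == "water"))
})
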