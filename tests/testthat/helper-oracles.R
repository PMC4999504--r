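# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's internal code paths: brute-force
# enumeration, closed forms, and textbook formulas only.

# --- brute-force periodic geometry -------------------------------------------

.image_shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

# minimum distance by explicit enumeration of the 27 periodic images
oracle_min_image_dist <- function(a, b, box) {
  sh <- .image_shifts %*% diag(box)
  min(sqrt(rowSums((matrix(a - b, 27, 3, byrow = TRUE) + sh)^2)))
}

# minimum-image unit vector from i to j by the same enumeration
oracle_min_image_dir <- function(from, to, box) {
  sh <- .image_shifts %*% diag(box)
  cand <- matrix(to - from, 27, 3, byrow = TRUE) + sh
  v <- cand[which.min(rowSums(cand^2)), ]
  v / sqrt(sum(v^2))
}

# full minimum-image distance matrix via the enumeration oracle
oracle_dist_matrix <- function(coords, box) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) d[i, j] <- d[j, i] <-
          oracle_min_image_dist(coords[i, ], coords[j, ], box)
    }
  }
  d
}

# --- Steinhardt q6 via the Legendre addition theorem -------------------------

# P6 Legendre polynomial, explicit coefficients
oracle_p6 <- function(x) (231 * x^6 - 315 * x^4 + 105 * x^2 - 5) / 16

# q6 of one particle from its neighbour unit vectors:
# q6^2 = (1/N^2) sum_jk P6(u_j . u_k)  (addition theorem; includes j = k)
oracle_q6_from_dirs <- function(u) {
  dots <- pmin(1, pmax(-1, tcrossprod(u)))
  sqrt(mean(oracle_p6(dots)))
}

# mean per-particle q6 over a configuration, neighbours by cutoff, with all
# distances from the 27-image enumeration
oracle_q6_mean <- function(coords, box, cutoff) {
  d <- oracle_dist_matrix(coords, box)
  vals <- numeric(0)
  for (i in seq_len(nrow(coords))) {
    nb <- which(d[i, ] <= cutoff & seq_len(nrow(coords)) != i)
    if (!length(nb)) next
    u <- t(vapply(nb, function(j) {
      oracle_min_image_dir(coords[i, ], coords[j, ], box)
    }, numeric(3)))
    vals <- c(vals, oracle_q6_from_dirs(u))
  }
  mean(vals)
}

# --- tetrahedral order from the defining sum ---------------------------------

oracle_qtet_from_dirs <- function(u) {
  s <- 0
  for (j in 1:3) for (k in (j + 1):4) {
    s <- s + (sum(u[j, ] * u[k, ]) + 1 / 3)^2
  }
  1 - 3 / 8 * s
}

oracle_qtet_mean <- function(coords, box) {
  d <- oracle_dist_matrix(coords, box)
  vals <- numeric(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    nb <- order(replace(d[i, ], i, Inf))[1:4]
    u <- t(vapply(nb, function(j) {
      oracle_min_image_dir(coords[i, ], coords[j, ], box)
    }, numeric(3)))
    vals[i] <- oracle_qtet_from_dirs(u)
  }
  mean(vals)
}

# --- exhaustive union-find clustering ----------------------------------------

oracle_cluster_sizes <- function(coords, mol, box, cutoff) {
  mols <- sort(unique(mol))
  parent <- seq_along(mols)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- nrow(coords)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (mol[i] == mol[j]) next
      if (oracle_min_image_dist(coords[i, ], coords[j, ], box) <= cutoff) {
        ri <- find(match(mol[i], mols)); rj <- find(match(mol[j], mols))
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_along(mols), find, integer(1))
  sort(as.numeric(table(roots)), decreasing = TRUE)
}

# --- exhaustive hydrogen-bond count ------------------------------------------

oracle_hbond_count <- function(fr, top, don, acc, d_cut, angle_cut) {
  bonds <- top$bonds
  cnt <- 0L
  for (d in don) {
    hs <- c(bonds[bonds[, 1] == d, 2], bonds[bonds[, 2] == d, 1])
    hs <- hs[top$atoms$element[hs] == "H"]
    for (a in acc) {
      if (a == d) next
      if (top$atoms$molecule_id[a] == top$atoms$molecule_id[d]) next
      da <- oracle_min_image_dist(fr$coords[d, ], fr$coords[a, ], fr$box)
      if (da > d_cut) next
      for (h in hs) {
        # angle at the donor, minimum-image vectors
        va <- fr$coords[a, ] - fr$coords[d, ]
        va <- va - fr$box * ceiling(va / fr$box - 0.5)
        vh <- fr$coords[h, ] - fr$coords[d, ]
        vh <- vh - fr$box * ceiling(vh / fr$box - 0.5)
        ang <- acos(max(-1, min(1, sum(va * vh) /
                                  sqrt(sum(va^2) * sum(vh^2))))) * 180 / pi
        if (ang <= angle_cut) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# --- fixture builders --------------------------------------------------------

# n rigid 3-site waters with oxygens at the given positions
make_waters <- function(opos, box = c(50, 50, 50), rotate = FALSE) {
  n <- nrow(opos)
  atoms <- data.frame(
    atom_id = seq_len(3 * n), name = rep(c("OW", "HW1", "HW2"), n),
    element = rep(c("O", "H", "H"), n),
    mass = rep(element_mass(c("O", "H", "H")), n),
    residue_name = "HOH", residue_index = rep(seq_len(n), each = 3),
    molecule_id = rep(seq_len(n), each = 3), group_tag = "water",
    stringsAsFactors = FALSE)
  tm <- rbind(c(0, 0, 0), c(0.9572, 0, 0),
              c(0.9572 * cos(104.52 * pi / 180),
                0.9572 * sin(104.52 * pi / 180), 0))
  xyz <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- if (rotate) tm %*% t(random_rotation()) else tm
    sweep(p, 2, opos[i, ], "+")
  }))
  bonds <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(c(3 * i - 2, 3 * i - 1), c(3 * i - 2, 3 * i))
  }))
  list(topology = topology(atoms, bonds), frame = new_frame(xyz, box))
}

# ideal L-alanine heavy-atom geometry (synthetic template; embedded 3-D
# coordinates of the L enantiomer)
l_alanine_template <- function() {
  rbind(N  = c(-0.8239,  1.1065, -0.7419),
        CA = c(-0.3507,  0.2334,  0.3576),
        C  = c( 1.1651,  0.0077,  0.2762),
        CB = c(-1.0943, -1.0937,  0.3023))
}

expect_series_equal <- function(series, value, tol = 1e-8) {
  testthat::expect_true(all(abs(series$values - value) < tol))
}
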