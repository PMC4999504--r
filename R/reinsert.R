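# Strategic water reinsertion: rejection sampling with per-region density
# targets plus an overall box-mean target, under a hard oxygen exclusion
# radius. Placement guarantees geometry only (no energy relaxation); the
# greedy exclusion acceptance runs in compiled code.

# rigid 3-site water template (O, H, H), O at the origin
.water_template <- function() {
  r_oh <- 0.9572; ang <- 104.52 * pi / 180
  rbind(c(0, 0, 0),
        c(r_oh, 0, 0),
        c(r_oh * cos(ang), r_oh * sin(ang), 0))
}

#' Reinsert water molecules with region density targets
#'
#' Rejection sampling of rigid 3-site waters: region targets are filled
#' first (`floor(target * volume / m_water)` molecules with the oxygen
#' inside each region), then the remainder of the box is filled outside all
#' target regions until the box-mean water density reaches
#' `overall_density`. No placed oxygen comes within `exclusion_radius` of
#' any existing atom or previously placed oxygen (minimum image).
#'
#' @param fr existing `frame` (solute; may already contain water).
#' @param top existing `topology`.
#' @param overall_density box-mean water mass density target, g/cc
#'   (default 1.0).
#' @param regions list of `list(region = region_spec, target = g/cc)`
#'   entries; may be empty.
#' @param exclusion_radius oxygen exclusion distance, Angstrom
#'   (default 2.4).
#' @param seed RNG seed.
#' @param max_reject consecutive-rejection limit before declaring the
#'   packing infeasible.
#' @return list with merged `topology` and `frame` plus `n_inserted` and
#'   `region_counts`.
#' @export
reinsert_water <- function(fr, top, overall_density = 1.0, regions = list(),
                           exclusion_radius = 2.4, seed,
                           max_reject = 1e5) {
  set.seed(seed)
  box <- fr$box
  mw <- hf_constants$water_mass * hf_constants$amu_g  # g per molecule
  n_total <- floor(overall_density * prod(box) * 1e-24 / mw)
  existing_w <- sum(top$atoms$group_tag == "water" & top$atoms$element == "O")
  fixed <- wrap_coords(fr$coords, box)
  oxy <- matrix(numeric(0), 0, 3)
  fill <- function(n_target, inside_fun, label) {
    placed <- 0L
    failed <- 0L
    while (placed < n_target) {
      B <- min(5e4, max(2000L, 4L * (n_target - placed)))
      cand <- cbind(stats::runif(B, 0, box[1]), stats::runif(B, 0, box[2]),
                    stats::runif(B, 0, box[3]))
      cand <- cand[inside_fun(cand), , drop = FALSE]
      acc <- if (nrow(cand)) {
        .accept_excluded(cand, rbind(fixed, oxy), box, exclusion_radius,
                         n_target - placed)
      } else integer(0)
      if (length(acc) == 0L) {
        failed <- failed + B
        if (failed > max_reject) {
          stop("packing infeasible in ", label, ": placed ", placed, " of ",
               n_target, " waters (achieved fraction ",
               signif(placed / n_target, 3), " of target)")
        }
        next
      }
      failed <- 0L
      oxy <<- rbind(oxy, cand[acc, , drop = FALSE])
      placed <- placed + length(acc)
    }
    placed
  }
  region_counts <- integer(0)
  for (rg in regions) {
    vol <- region_volume(rg$region, box)
    n_r <- floor(rg$target * vol * 1e-24 / mw)
    region_counts <- c(region_counts,
                       fill(n_r, function(p) region_contains(rg$region, p, box),
                            paste0("region ", rg$region$kind)))
  }
  n_rest <- n_total - existing_w - nrow(oxy)
  if (n_rest > 0L) {
    outside <- function(p) {
      keep <- rep(TRUE, nrow(p))
      for (rg in regions) {
        keep <- keep & !region_contains(rg$region, p, box)
      }
      keep
    }
    fill(n_rest, outside, "bulk")
  }
  nW <- nrow(oxy)
  if (nW == 0L) stop("no waters to insert (already at target density)")
  tmpl <- .water_template()
  xyz <- matrix(0, 3L * nW, 3)
  for (i in seq_len(nW)) {
    pts <- tmpl %*% t(random_rotation())
    xyz[(3 * i - 2):(3 * i), ] <- sweep(pts, 2, oxy[i, ], "+")
  }
  xyz <- wrap_coords(xyz, box)
  n0 <- n_atoms(top)
  mol0 <- max(top$atoms$molecule_id)
  res0 <- max(top$atoms$residue_index)
  watoms <- data.frame(
    atom_id = n0 + seq_len(3L * nW),
    name = rep(c("OW", "HW1", "HW2"), nW),
    element = rep(c("O", "H", "H"), nW),
    mass = rep(element_mass(c("O", "H", "H")), nW),
    residue_name = "HOH",
    residue_index = res0 + rep(seq_len(nW), each = 3L),
    molecule_id = mol0 + rep(seq_len(nW), each = 3L),
    group_tag = "water", stringsAsFactors = FALSE)
  wbonds <- cbind(n0 + 3L * (seq_len(nW) - 1L) + 1L,
                  n0 + 3L * (seq_len(nW) - 1L) + 2L)
  wbonds <- rbind(wbonds, cbind(wbonds[, 1], wbonds[, 1] + 2L))
  atoms <- rbind(top$atoms, watoms)
  bonds <- rbind(top$bonds, wbonds)
  new_top <- topology(atoms, bonds)
  new_fr <- new_frame(rbind(fr$coords, xyz), box, time = fr$time)
  list(topology = new_top, frame = new_fr, n_inserted = nW,
       region_counts = region_counts)
}
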