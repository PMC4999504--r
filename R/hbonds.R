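# Geometric hydrogen-bond detection.

#' Find hydrogen bonds by the geometric criterion
#'
#' A bond donor-H...acceptor is listed iff the donor-acceptor minimum-image
#' distance is at most `d_cut` and the H-donor-acceptor angle is at most
#' `angle_cut`. Hydrogens are taken from the topology's bond list; a donor
#' without bonded hydrogens is an error.
#'
#' @param fr a `frame`.
#' @param top the matching `topology`.
#' @param donors selection (expression or ids) of donor heavy atoms.
#' @param acceptors selection of acceptor atoms.
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut H-donor-acceptor angle cutoff, degrees (default 30).
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle`.
#' @export
find_hbonds <- function(fr, top, donors, acceptors, d_cut = 3.5,
                        angle_cut = 30) {
  don <- .resolve_sel(top, fr, donors, "donor selection")
  acc <- .resolve_sel(top, fr, acceptors, "acceptor selection")
  bonds <- top$bonds
  hyd_of <- function(d) {
    nb <- c(bonds[bonds[, 1] == d, 2], bonds[bonds[, 2] == d, 1])
    nb[top$atoms$element[nb] %in% c("H", "D")]
  }
  hs <- lapply(don, hyd_of)
  bad <- don[vapply(hs, length, integer(1)) == 0L]
  if (length(bad)) {
    stop("donor atom(s) without bonded hydrogens: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- list()
  dmat <- min_image_dist(fr$coords[don, , drop = FALSE],
                         fr$coords[acc, , drop = FALSE], fr$box)
  for (i in seq_along(don)) {
    d <- don[i]
    cand <- acc[dmat[i, ] <= d_cut & acc != d]
    if (!length(cand)) next
    for (a in cand) {
      if (top$atoms$molecule_id[a] == top$atoms$molecule_id[d]) next
      va <- minimum_image_displacement(fr$coords[a, ], fr$coords[d, ], fr$box)
      for (h in hs[[i]]) {
        vh <- minimum_image_displacement(fr$coords[h, ], fr$coords[d, ], fr$box)
        cosang <- sum(va * vh) / sqrt(sum(va^2) * sum(vh^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang <= angle_cut) {
          out[[length(out) + 1L]] <- data.frame(
            donor = d, hydrogen = h, acceptor = a,
            distance = sqrt(sum(va^2)), angle = ang)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, out)
}
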