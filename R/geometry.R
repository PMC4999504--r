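# Shared geometry helpers: dihedrals, internal-coordinate atom placement,
# random rotations and uniform sphere sampling (Marsaglia method).

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking down the b-c bond, a positive angle is a
#' clockwise rotation of the far bond relative to the near bond. Returned in
#' degrees in (-180, 180].
#'
#' @param a,b,c,d numeric 3-vectors, Angstrom.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- c - b
  b2 <- d - c
  b1n <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1n) * b1n
  w <- b2 - sum(b2 * b1n) * b1n
  x <- sum(v * w)
  y <- sum(crossprod3(b1n, v) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Place an atom from internal coordinates
#'
#' Natural-extension placement: the new atom `d` is positioned at the given
#' bond length from `c`, bond angle `b-c-d`, and dihedral `a-b-c-d`
#' (IUPAC convention, consistent with [dihedral_angle()]).
#'
#' @param a,b,c reference positions (3-vectors).
#' @param bond length c-d, Angstrom.
#' @param angle angle b-c-d, degrees.
#' @param dihedral dihedral a-b-c-d, degrees.
#' @return position of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- crossprod3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- crossprod3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Uniform points on the unit sphere (Marsaglia 1972)
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_sample <- function(n) {
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- 2L * (n - got)
    u <- stats::runif(m, -1, 1)
    v <- stats::runif(m, -1, 1)
    s <- u * u + v * v
    ok <- which(s < 1)
    take <- ok[seq_len(min(length(ok), n - got))]
    if (length(take)) {
      r <- sqrt(1 - s[take])
      out[(got + 1):(got + length(take)), ] <-
        cbind(2 * u[take] * r, 2 * v[take] * r, 1 - 2 * s[take])
      got <- got + length(take)
    }
  }
  out
}

#' Uniform random 3-D rotation matrix
#'
#' Built from a uniformly sampled axis and a uniform angle composed twice,
#' via QR of a Gaussian matrix (Haar measure, sign-fixed).
#'
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
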