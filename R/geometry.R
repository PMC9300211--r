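# Internal 3-D geometry primitives. Coordinates in Angstrom, angles in
# degrees at every exported interface; radians only inside this file.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle at vertex b of the triple a-b-c, in degrees
#' @noRd
angle3 <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed dihedral a-b-c-d in degrees, IUPAC convention
#'
#' Looking along b->c, the angle is positive when a->b->c->d is clockwise;
#' the sign comes from the triple product (b1 x b2) . b3 via atan2.
#' Range (-180, 180].
#' @noRd
dihedral4 <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- unit(c - b)
  b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(cross3(b1, v) * w)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place a new atom by internal coordinates (natural extension of
#' reference frame): the new atom X is bonded to c, with |X-c| = bond,
#' angle X-c-b = angle (deg), and dihedral X-c-b-a = torsion (deg).
#' @noRd
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  # local displacement in the frame of c
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  # columns: bc, m, n
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Random rotation matrix, uniform over SO(3)
#' @noRd
random_rotation <- function() {
  # QR of a Gaussian matrix with sign fix
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Optimal rigid superposition RMSD (Kabsch) between two coordinate
#' matrices (n x 3), used for round-trip checks.
#' @noRd
kabsch_rmsd <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diffs <- yc %*% r - xc
  sqrt(mean(rowSums(diffs^2)))
}
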