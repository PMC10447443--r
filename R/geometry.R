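# Torsion angles, minimum-image displacements and rigid-body placement.

#' Signed dihedral (torsion) angle
#'
#' Standard signed torsion about the p2-p3 axis under the IUPAC right-hand
#' convention, returned in degrees in (-180, 180]. The angle is invariant
#' under rigid rotation and translation of all four points and symmetric
#' under reversal of the point order.
#'
#' @param p1,p2,p3,p4 numeric(3) Cartesian coordinates in Angstrom.
#' @return angle in degrees in (-180, 180].
#' @examples
#' dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))  # 0 (cis)
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nb2 <- .norm3(b2)
  if (nb2 < 1e-10 || .norm3(b1) < 1e-10 || .norm3(b3) < 1e-10)
    stop("degenerate dihedral geometry: consecutive points coincide")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-10 || .norm3(n2) < 1e-10)
    stop("degenerate dihedral geometry: collinear triple")
  m1 <- .cross3(n1, b2 / nb2)
  ang <- .deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360  # (-180, 180] convention
  ang
}

#' Minimum-image displacement vector
#'
#' Returns r2 - r1 shifted by the lattice translation minimizing its norm.
#' The wrapped image and its 27-neighbour shell are searched, which is exact
#' for cells whose shortest lattice vector exceeds twice the distance of
#' interest.
#'
#' @param cell a \linkS4class{PeriodicCell}.
#' @param r1,r2 numeric(3) Cartesian coordinates in Angstrom.
#' @return numeric(3) displacement in Angstrom.
#' @examples
#' cell <- periodicCell(20)
#' minimumImageVector(cell, c(1, 1, 1), c(19, 1, 1))  # c(-2, 0, 0)
#' @export
minimumImageVector <- function(cell, r1, r2) {
  L <- cell@lattice
  f <- (r2 - r1) %*% solve(L)
  f <- f - round(f)
  best <- NULL
  bestN <- Inf
  for (k in seq_len(nrow(.shifts27))) {
    d <- drop((f + .shifts27[k, ]) %*% L)
    n <- sum(d * d)
    if (n < bestN) {
      bestN <- n
      best <- d
    }
  }
  best
}

## Rigid-body atom placement (NeRF): position of atom D bonded to C with
## |D - C| = bond, angle(D, C, B) = angleDeg and dihedral(D, C, B, A) =
## dihedralDeg. Used by the synthetic molecule builder.
.placeAtom <- function(a, b, c., bond, angleDeg, dihedralDeg) {
  theta <- .rad(angleDeg)
  phi <- .rad(dihedralDeg)
  bc <- c. - b
  bc <- bc / .norm3(bc)
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / .norm3(n)
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(theta), bond * sin(theta) * cos(phi),
          -bond * sin(theta) * sin(phi))
  c. + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
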