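# Internal numerical helpers shared across modules.

.norm3 <- function(v) sqrt(sum(v * v))

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.deg <- function(x) x * 180 / pi
.rad <- function(x) x * pi / 180

## 27 integer lattice shifts (the wrapped image plus its first shell)
.shifts27 <- local({
  g <- expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)
  as.matrix(g)
})

.isOrthorhombic <- function(lattice, tol = 1e-10) {
  all(abs(lattice[upper.tri(lattice)]) < tol) &&
    all(abs(lattice[lower.tri(lattice)]) < tol)
}

## Uniform random proper rotation matrices (QR of a Gaussian matrix, det fixed)
.randomRotation <- function() {
  qr. <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  R <- qr.Q(qr.)
  R <- R %*% diag(sign(diag(qr.R(qr.))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

## All minimum-image distances between two sets of points given in fractional
## coordinates. Exact component-wise wrap for orthorhombic lattices; otherwise
## the wrapped image plus its 27-neighbour shell is searched (exact for
## diagonal-dominant cells whose shortest lattice vector exceeds twice any
## distance of interest).
.pairDistances <- function(lattice, fracA, fracB) {
  nA <- nrow(fracA)
  nB <- nrow(fracB)
  w1 <- outer(fracA[, 1L], fracB[, 1L], "-")
  w2 <- outer(fracA[, 2L], fracB[, 2L], "-")
  w3 <- outer(fracA[, 3L], fracB[, 3L], "-")
  w1 <- w1 - round(w1)
  w2 <- w2 - round(w2)
  w3 <- w3 - round(w3)
  if (.isOrthorhombic(lattice)) {
    d2 <- (w1 * lattice[1L, 1L])^2 + (w2 * lattice[2L, 2L])^2 +
      (w3 * lattice[3L, 3L])^2
  } else {
    d2 <- NULL
    for (k in seq_len(nrow(.shifts27))) {
      f1 <- w1 + .shifts27[k, 1L]
      f2 <- w2 + .shifts27[k, 2L]
      f3 <- w3 + .shifts27[k, 3L]
      x <- f1 * lattice[1L, 1L] + f2 * lattice[2L, 1L] + f3 * lattice[3L, 1L]
      y <- f1 * lattice[1L, 2L] + f2 * lattice[2L, 2L] + f3 * lattice[3L, 2L]
      z <- f1 * lattice[1L, 3L] + f2 * lattice[2L, 3L] + f3 * lattice[3L, 3L]
      dk <- x * x + y * y + z * z
      d2 <- if (is.null(d2)) dk else pmin(d2, dk)
    }
  }
  dim(d2) <- c(nA, nB)
  sqrt(d2)
}

.cartToFrac <- function(lattice, coords) {
  coords %*% solve(lattice)
}

.fracToCart <- function(lattice, frac) {
  frac %*% lattice
}

## Deterministic per-stage seed fan-out from one master seed (kept < 2^31)
.deriveSeed <- function(seed, stage) {
  (as.integer(seed) * 1103L + as.integer(stage) * 12289L) %% 2147483629L
}

.envKey <- function(trajectory, frame, moleculeId) {
  paste(trajectory, frame, moleculeId, sep = ":")
}
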