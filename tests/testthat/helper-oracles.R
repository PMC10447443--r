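# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately written as brute-force re-implementations, independent of the
# package's production code paths.

## brute-force minimum-image distance over a 5^3 periodic image enumeration
bruteMinImageDist <- function(lattice, r1, r2) {
  best <- Inf
  for (i in -2:2) for (j in -2:2) for (k in -2:2) {
    d <- r2 - r1 + i * lattice[1, ] + j * lattice[2, ] + k * lattice[3, ]
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

## brute-force molecule-contact membership for one snapshot
bruteMembership <- function(snap, cutoff) {
  a <- atoms(snap)
  L <- cellLattice(snap@cell)
  mols <- sort(unique(a$moleculeId))
  adj <- matrix(FALSE, length(mols), length(mols),
                dimnames = list(mols, mols))
  for (mi in seq_along(mols)) for (mj in seq_len(mi)) {
    ai <- a[a$moleculeId == mols[mi], , drop = FALSE]
    aj <- a[a$moleculeId == mols[mj], , drop = FALSE]
    hit <- FALSE
    for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(aj))) {
      if (bruteMinImageDist(L, c(ai$x[p], ai$y[p], ai$z[p]),
                            c(aj$x[q], aj$y[q], aj$z[q])) <= cutoff) {
        hit <- TRUE
        break
      }
    }
    adj[mi, mj] <- adj[mj, mi] <- hit
  }
  adj
}

## random diagonal-dominant (moderately skewed) triclinic cell
randomCell <- function(side = 12) {
  L <- diag(stats::runif(3, side, 1.4 * side))
  L[lower.tri(L)] <- stats::runif(3, -0.15 * side, 0.15 * side)
  periodicCell(L)
}

## snapshot of rigid triatomic molecules at given center positions
triatomicSnapshot <- function(centers, cell, trajectory = 1L, frame = 1L) {
  tmpl <- triatomicTemplate()
  rows <- lapply(seq_len(nrow(centers)), function(m) {
    a <- tmpl$atoms
    a$x <- a$x + centers[m, 1]
    a$y <- a$y + centers[m, 2]
    a$z <- a$z + centers[m, 3]
    a$moleculeId <- m
    a
  })
  a <- do.call(rbind, rows)
  a$atomId <- seq_len(nrow(a))
  snapshot(cell, a, tmpl$topology, c(trajectory, frame))
}

## two diatomic molecules with closest-atom separation `sep` along x
diatomicPairSnapshot <- function(sep, cellSide = 40) {
  topo <- molecularTopology(c("X1", "X2"),
                            c(X1 = "C", X2 = "C"),
                            bonds = rbind(c("X1", "X2")))
  a <- data.frame(
    element = "C",
    x = c(0, 1.5, 1.5 + sep, 3 + sep), y = 0, z = 0,
    siteLabel = rep(c("X1", "X2"), 2L),
    moleculeId = rep(1:2, each = 2L),
    atomId = 1:4)
  snapshot(periodicCell(cellSide), a, topo, c(1L, 1L))
}

## hand-built local environment: central O-H donor plus point acceptors.
## acceptors: data.frame(element, siteLabel, x, y, z), one molecule each.
donorEnvironment <- function(acceptors) {
  central <- data.frame(
    element = c("O", "H"), x = c(0, 0.97), y = 0, z = 0,
    siteLabel = c("O1", "H1"), moleculeId = 1L, atomId = 1:2)
  acc <- data.frame(
    element = acceptors$element, x = acceptors$x, y = acceptors$y,
    z = acceptors$z, siteLabel = acceptors$siteLabel,
    moleculeId = 1L + seq_len(nrow(acceptors)),
    atomId = 2L + seq_len(nrow(acceptors)))
  new("LocalEnvironment", atoms = rbind(central, acc),
      centralMoleculeId = 1L,
      memberMoleculeIds = c(1L, acc$moleculeId),
      cutoff = 7, sourceId = c(1L, 1L))
}

## minimal donor topology for the hand-built environments
donorTopology <- function() {
  molecularTopology(
    c("O1", "H1"), c(O1 = "O", H1 = "H"),
    bonds = rbind(c("O1", "H1")),
    hbondDonor = c("O1", "H1"),
    hbondAcceptors = data.frame(siteLabel = character(0),
                                element = character(0)))
}

## acceptor position at distance d from H (at (0.97,0,0)) with O-H-X angle
## `angleDeg`, in the xy-plane
acceptorAt <- function(d, angleDeg, element = "O", siteLabel = "OX") {
  h <- c(0.97, 0, 0)
  phi <- (180 - angleDeg) * pi / 180
  x <- h + d * c(cos(phi), sin(phi), 0)
  data.frame(element = element, siteLabel = siteLabel,
             x = x[1], y = x[2], z = x[3])
}
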